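#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `father_id`, `mother_id`, `sex`, `phenotype`, `sequenced`,
#' `sampled`. Unknown parents are `NA`. Phenotype `"unknown"` is used for
#' individuals whose disease status must not count as evidence (e.g. benign
#' goiter carriers in a thyroid-cancer kindred, or members too young to have
#' expressed a late-onset phenotype).
#'
#' @param id character vector of unique individual identifiers.
#' @param father_id,mother_id character vectors of parental ids (`NA` or
#'   `"0"` for unknown/founder).
#' @param sex one of `"male"`, `"female"`, `"unknown"` per individual.
#' @param phenotype one of `"affected"`, `"unaffected"`, `"unknown"`.
#' @param sequenced,sampled logical flags: exome-sequenced / DNA available.
#' @return An object of class `pedigree` (a data frame).
#' @export
pedigree <- function(id, father_id = NA_character_, mother_id = NA_character_,
                     sex = "unknown", phenotype = "unknown",
                     sequenced = FALSE, sampled = FALSE) {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    father_id = rep_len(as.character(father_id), n),
    mother_id = rep_len(as.character(mother_id), n),
    sex = rep_len(as.character(sex), n),
    phenotype = rep_len(as.character(phenotype), n),
    sequenced = rep_len(as.logical(sequenced), n),
    sampled = rep_len(as.logical(sampled), n),
    stringsAsFactors = FALSE
  )
  df$father_id[df$father_id %in% c("0", "")] <- NA_character_
  df$mother_id[df$mother_id %in% c("0", "")] <- NA_character_
  validate_pedigree(df)
  class(df) <- c("pedigree", "data.frame")
  df
}

validate_pedigree <- function(df) {
  if (nrow(df) == 0L) stop("no individuals")
  if (anyDuplicated(df$id)) {
    stop("duplicate id: ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  for (col in c("father_id", "mother_id")) {
    ref <- df[[col]]
    bad <- !is.na(ref) & !(ref %in% df$id)
    if (any(bad)) stop("unresolvable parent id: ", paste(unique(ref[bad]), collapse = ", "))
  }
  if (!all(df$sex %in% c("male", "female", "unknown"))) stop("invalid sex code")
  if (!all(df$phenotype %in% c("affected", "unaffected", "unknown"))) {
    stop("invalid phenotype code")
  }
  # acyclicity: repeatedly strip individuals whose parents are all stripped
  remaining <- df$id
  repeat {
    keep <- df$id %in% remaining
    strippable <- df$id[keep &
      (is.na(df$father_id) | !(df$father_id %in% remaining)) &
      (is.na(df$mother_id) | !(df$mother_id %in% remaining))]
    if (length(strippable) == 0L) break
    remaining <- setdiff(remaining, strippable)
  }
  if (length(remaining) > 0L) {
    stop("cycle detected involving: ", paste(remaining, collapse = ", "))
  }
  invisible(df)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf(
    "pedigree: %d individuals (%d affected, %d unaffected, %d unknown), %d founders\n",
    nrow(x), sum(x$phenotype == "affected"), sum(x$phenotype == "unaffected"),
    sum(x$phenotype == "unknown"), sum(is.na(x$father_id) & is.na(x$mother_id))
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Founder ids of a pedigree (both parents unknown)
#' @param ped a [pedigree()].
#' @return character vector of ids.
#' @export
founders <- function(ped) ped$id[is.na(ped$father_id) & is.na(ped$mother_id)]

#' Read a pedigree from a PED file
#'
#' Whitespace-delimited, 6 or more columns: family id (ignored), individual
#' id, father id, mother id, sex (1 = male, 2 = female, 0 = unknown),
#' phenotype (2 = affected, 1 = unaffected, 0 or -9 = unknown). An optional
#' 7th column is the sequenced flag (0/1) and an optional 8th the sampled
#' flag (0/1). A parent id of "0" means unknown.
#'
#' @param path file path.
#' @return a [pedigree()].
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", comment.char = "#"),
    error = function(e) data.frame())
  if (nrow(raw) == 0L) stop("no individuals")
  if (ncol(raw) < 6L) stop("PED file needs >= 6 columns")
  sex <- c(`1` = "male", `2` = "female", `0` = "unknown")[raw[[5]]]
  sex[is.na(sex)] <- "unknown"
  phen <- rep("unknown", nrow(raw))
  phen[raw[[6]] == "2"] <- "affected"
  phen[raw[[6]] == "1"] <- "unaffected"
  seqd <- if (ncol(raw) >= 7L) raw[[7]] == "1" else FALSE
  samp <- if (ncol(raw) >= 8L) raw[[8]] == "1" else seqd
  pedigree(id = raw[[2]], father_id = raw[[3]], mother_id = raw[[4]],
           sex = sex, phenotype = phen, sequenced = seqd, sampled = samp)
}

#' Write a pedigree to a PED file
#'
#' Emits the 8-column dialect read by [read_ped()] (family id fixed to
#' "FAM1"); read/write round-trips losslessly.
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @export
write_ped <- function(ped, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  phen <- c(affected = "2", unaffected = "1", unknown = "0")[ped$phenotype]
  out <- data.frame(
    fam = "FAM1", id = ped$id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = sex, phen = phen,
    sequenced = as.integer(ped$sequenced),
    sampled = as.integer(ped$sampled)
  )
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
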