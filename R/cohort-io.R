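#' Read a pedigree file
#'
#' Parses a whitespace-delimited pedigree file in the 6-column linkage
#' convention (`family_id individual_id father_id mother_id sex affection`)
#' with two optional extension columns: a 7th column flagging the
#' exome-sequenced discovery set (`1`/`0`) and an 8th free-text column of
#' Cobb angles in degrees (comma-separated; `.` = none recorded).
#'
#' Codes: sex `1` = male, `2` = female, other = unknown; affection `2` =
#' affected, `1` = unaffected, `3` = confirmed negative (examined
#' radiographically and found unaffected), `0`/`-9` = unknown; parent id
#' `0` = founder/unknown (stored as `NA`).  When the 7th column is absent,
#' `sequenced` defaults to `FALSE` for everyone — membership in the
#' discovery set must be stated explicitly, because the shared-by-all rule
#' of the filter cascade quantifies over sequenced members only.
#'
#' @param path pedigree file path.
#' @return A [FamilyCohort-class] object.
#' @seealso [writePedigree()] for the inverse.
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("A\tF\t0\t0\t1\t1", "A\tM\t0\t0\t2\t1",
#'              "A\tC\tF\tM\t2\t2\t1\t24"), ped)
#' readPedigree(ped)
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop(sprintf("pedigree file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("pedigree file is empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop(sprintf("pedigree line %d has %d fields; at least 6 required",
                 which(nf < 6)[1], min(nf)))
  }
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  fam <- get(1); iid <- get(2); fid <- get(3); mid <- get(4)
  key <- paste(fam, iid, sep = "/")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate individual_id within a family: %s",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  df <- data.frame(
    family_id = fam, individual_id = iid,
    father_id = ifelse(fid == "0", NA_character_, fid),
    mother_id = ifelse(mid == "0", NA_character_, mid),
    sex = c("1" = "male", "2" = "female")[get(5)],
    affection = c("1" = "unaffected", "2" = "affected",
                  "3" = "confirmed_negative")[get(6)],
    stringsAsFactors = FALSE
  )
  df$sex[is.na(df$sex)] <- "unknown"
  df$affection[is.na(df$affection)] <- "unknown"
  seqcol <- get(7)
  df$sequenced <- !is.na(seqcol) & seqcol == "1"
  cobb <- get(8)
  df$cobb <- lapply(cobb, function(s) {
    if (is.na(s) || s == "." || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ",")[[1]])
  })
  # parent resolution errors name the offending id
  for (side in c("father_id", "mother_id")) {
    pid <- df[[side]]
    bad <- !is.na(pid) & !(paste(df$family_id, pid, sep = "/") %in% key)
    if (any(bad)) {
      stop(sprintf("%s '%s' not found in family '%s'",
                   sub("_id", "", side), pid[bad][1], df$family_id[bad][1]))
    }
  }
  FamilyCohort(df)
}

#' Write a pedigree file
#'
#' Writes a [FamilyCohort-class] in the 8-column format read by
#' [readPedigree()]; reading the result back yields a structurally
#' identical cohort.
#'
#' @param cohort a `FamilyCohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(cohort, path) {
  df <- members(cohort)
  sexCode <- c(male = "1", female = "2", unknown = "0")[df$sex]
  affCode <- c(unaffected = "1", affected = "2", confirmed_negative = "3",
               unknown = "0")[df$affection]
  cobb <- vapply(df$cobb, function(a) {
    if (!length(a)) "." else paste(format(a, trim = TRUE), collapse = ",")
  }, character(1))
  out <- data.frame(df$family_id, df$individual_id,
                    ifelse(is.na(df$father_id), "0", df$father_id),
                    ifelse(is.na(df$mother_id), "0", df$mother_id),
                    sexCode, affCode, as.integer(df$sequenced), cobb)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One term per tab-delimited line: term id, description, then one or more
#' member gene symbols.  Symbols are uppercase-normalized and deduplicated
#' within a term.
#'
#' @param path GMT file path.
#' @return A [TermSets-class] object.
#' @seealso [writeTermSets()] for the inverse.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("GO:0005874\tmicrotubule\tINVS\tDNAH1", gmt)
#' readTermSets(gmt)
#' @export
readTermSets <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("GMT line %d has %d fields; term id, description and >= 1 gene required",
                 which(keep)[which(nf < 3)[1]], nf[nf < 3][1]))
  }
  TermSets(
    term_ids = vapply(fields, `[`, character(1), 1),
    term_names = vapply(fields, `[`, character(1), 2),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write gene sets to a GMT file
#'
#' @param termSets a [TermSets-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTermSets <- function(termSets, path) {
  lines <- mapply(function(id, nm, g) {
    paste(c(id, nm, g), collapse = "\t")
  }, termIds(termSets), termNames(termSets), termGenes(termSets))
  writeLines(unname(lines), path)
  invisible(path)
}
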