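## Delimited-table I/O for titrations, time courses and reports.
## Long format, one measurement per row:
##   series_id  variant  lesion  E0_uM|t_s  replicate  value

#' Write/read a titration series as a delimited table
#'
#' Long tab-separated format with columns series_id, variant, lesion,
#' E0_uM, replicate, value. Design metadata (DNA concentration, noise,
#' seed) travels in `# key: value` header comments so a round trip
#' restores the full object.
#'
#' @param series a [TitrationSeries-class]
#' @param path output file
#' @return `path`, invisibly (writer); a [TitrationSeries-class] (reader)
#' @export
writeTitrationTable <- function(series, path) {
  stopifnot(is(series, "TitrationSeries"))
  d <- series@design
  hdr <- c(sprintf("# dnaConc: %.10g", d@dnaConc),
           sprintf("# noiseSd: %.10g", d@noiseSd),
           sprintf("# seed: %d", d@seed))
  tab <- data.frame(series_id = paste(series@variant, series@lesion, sep = "_"),
                    variant = series@variant, lesion = series@lesion,
                    E0_uM = series@points$E0,
                    replicate = series@points$replicate,
                    value = series@points$F)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(tab, path, append = TRUE, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

.readHeaderMeta <- function(path) {
  lines <- readLines(path, n = 10L)
  lines <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#\\s*", "", lines), ":\\s*")
  stats::setNames(lapply(kv, function(x) x[2]), vapply(kv, `[`, "", 1))
}

#' @rdname writeTitrationTable
#' @export
readTitrationTable <- function(path) {
  meta <- .readHeaderMeta(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  design <- TitrationDesign(enzymeConcs = sort(unique(tab$E0_uM)),
                            dnaConc = as.numeric(meta$dnaConc %||% 1.2),
                            replicates = max(tab$replicate),
                            noiseSd = as.numeric(meta$noiseSd %||% 0),
                            seed = as.integer(meta$seed %||% 1))
  new("TitrationSeries", variant = tab$variant[1], lesion = tab$lesion[1],
      design = design,
      points = data.frame(E0 = tab$E0_uM, F = tab$value,
                          replicate = tab$replicate))
}

#' Write/read a time course as a delimited table
#'
#' Long tab-separated format with columns series_id, variant, lesion, t_s,
#' replicate, value; E0/S0 travel in header comments.
#'
#' @param tc a [TimeCourse-class]
#' @param path output file
#' @return `path`, invisibly (writer); a [TimeCourse-class] (reader)
#' @export
writeTimeCourseTable <- function(tc, path) {
  stopifnot(is(tc, "TimeCourse"))
  hdr <- c(sprintf("# E0: %.10g", tc@E0), sprintf("# S0: %.10g", tc@S0))
  tab <- data.frame(series_id = paste(tc@variant, tc@lesion, sep = "_"),
                    variant = tc@variant, lesion = tc@lesion,
                    t_s = tc@points$t, replicate = 1L,
                    value = tc@points$P)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(tab, path, append = TRUE, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname writeTimeCourseTable
#' @export
readTimeCourseTable <- function(path) {
  meta <- .readHeaderMeta(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  new("TimeCourse", variant = tab$variant[1], lesion = tab$lesion[1],
      E0 = as.numeric(meta$E0 %||% 1), S0 = as.numeric(meta$S0 %||% 1),
      points = data.frame(t = tab$t_s, P = tab$value))
}

#' Write a contact table as a delimited report
#'
#' @param ct a [ContactTable-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeContactTable <- function(ct, path) {
  stopifnot(is(ct, "ContactTable"))
  rec <- ct@records
  rec$minDist <- round(rec$minDist, 3)
  suppressWarnings(utils::write.table(rec, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}
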