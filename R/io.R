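# Plain-text readers and writers: TSV tables, SWC morphologies, matrix
# images, and JSON configs. Everything this package consumes or emits is
# text, so runs are diffable and portable.

#' Read / write a TSV table
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table` returns a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an SWC morphology
#'
#' Standard whitespace-separated SWC: `id type x y z radius parent`, `#`
#' comments.
#'
#' @param path file path.
#' @param swc data.frame with the seven SWC columns.
#' @return `read_swc` returns a data.frame with SWC columns.
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  if (sum(df$parent == -1L) != 1L)
    stop("SWC must have exactly one root", call. = FALSE)
  df
}

#' @rdname read_swc
#' @export
write_swc <- function(swc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  utils::write.table(swc[, c("id", "type", "x", "y", "z", "radius", "parent")],
                     con, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write an intensity image as a plain-text matrix
#'
#' Tab-separated rows of numbers; row 1 is the top of the image (the pia in
#' the synthetic fixtures). Used in place of binary TIFF so fixtures remain
#' text.
#'
#' @param path file path.
#' @param image numeric matrix.
#' @return `read_image_tsv` returns a matrix.
#' @export
read_image_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
}

#' @rdname read_image_tsv
#' @export
write_image_tsv <- function(image, path) {
  utils::write.table(image, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration (JSON)
#'
#' @param path JSON file path.
#' @return named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
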