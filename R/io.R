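# JSONL / CSV / TSV readers and writers for the pipeline's interchange
# formats. One JSON object per line; field order follows the tibble.

#' Write a tibble as JSON lines
#'
#' @param df data frame.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_jsonl <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(r)
    as.character(jsonlite::toJSON(as.list(df[r, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read JSON lines into a tibble
#'
#' @param path input file.
#' @return tibble, one row per line.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(tibble::tibble())
  rows <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e)
               stop("malformed JSONL record at line ", i, " of ", path,
                    ": ", conditionMessage(e), call. = FALSE))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
}

#' Write criterion labels (or scores) as CSV
#'
#' @param labels tibble with id and c1..c7 (optionally score/band).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_labels_csv <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read criterion labels from CSV
#'
#' @param path input file.
#' @return tibble.
#' @export
read_labels_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a follower edge list as 2-column TSV
#'
#' @param edges tibble follower_id/followed_id.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_edges_tsv <- function(edges, path) {
  write.table(edges[, c("follower_id", "followed_id")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a follower edge list from TSV
#'
#' @param path input file.
#' @return tibble follower_id/followed_id.
#' @export
read_edges_tsv <- function(path) {
  tibble::as_tibble(read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character"))
}
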