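#' Write a simulated run as paired FASTQ files
#'
#' Emits `<prefix>_reads.fastq` (inserts) and `<prefix>_index.fastq`
#' (index reads) with matching read ids. Array coordinates and UIDs travel
#' in the header as `XY:x,y` and `UID:seq` tags.
#'
#' @param run A `sim_run`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_run_fastq <- function(run, prefix) {
  stopifnot(inherits(run, "sim_run"))
  r <- run$reads
  hdr <- sprintf("%s XY:%d,%d", r$read_id, r$x, r$y)
  has_uid <- !is.na(r$uid)
  hdr[has_uid] <- paste0(hdr[has_uid], " UID:", r$uid[has_uid])
  paths <- c(reads = paste0(prefix, "_reads.fastq"),
             index = paste0(prefix, "_index.fastq"))
  ins <- Biostrings::DNAStringSet(r$insert_seq); names(ins) <- hdr
  Biostrings::writeXStringSet(ins, paths[["reads"]], format = "fastq",
                              qualities = Biostrings::BStringSet(r$insert_quals))
  idx <- Biostrings::DNAStringSet(r$index_seq); names(idx) <- hdr
  Biostrings::writeXStringSet(idx, paths[["index"]], format = "fastq",
                              qualities = Biostrings::BStringSet(r$index_quals))
  invisible(paths)
}

#' Read paired insert/index FASTQ files back into a read table
#'
#' Inverse of [write_run_fastq()]: pairs the two files by order, checks the
#' read ids agree, and recovers `XY:`/`UID:` header tags.
#'
#' @param reads_path,index_path FASTQ paths.
#' @return Data frame in the layout of a `sim_run`'s `reads` element.
#' @export
read_run_fastq <- function(reads_path, index_path) {
  ins <- Biostrings::readDNAStringSet(reads_path, format = "fastq",
                                      with.qualities = TRUE)
  idx <- Biostrings::readDNAStringSet(index_path, format = "fastq",
                                      with.qualities = TRUE)
  if (length(ins) != length(idx)) stop("FASTQ files differ in read count")
  parse_hdr <- function(h) {
    parts <- strsplit(h, " ", fixed = TRUE)
    id <- vapply(parts, `[`, character(1), 1L)
    grab <- function(tag) vapply(parts, function(p) {
      hit <- grep(paste0("^", tag, ":"), p, value = TRUE)
      if (length(hit)) sub(paste0("^", tag, ":"), "", hit[1]) else
        NA_character_
    }, character(1))
    list(id = id, xy = grab("XY"), uid = grab("UID"))
  }
  hi <- parse_hdr(names(ins)); hx <- parse_hdr(names(idx))
  if (!identical(hi$id, hx$id))
    stop("read ids differ between insert and index FASTQ")
  xy <- strsplit(hi$xy, ",", fixed = TRUE)
  data.frame(read_id = hi$id,
             insert_seq = as.character(ins),
             insert_quals = as.character(S4Vectors::mcols(ins)$qualities),
             index_seq = as.character(idx),
             index_quals = as.character(S4Vectors::mcols(idx)$qualities),
             x = as.integer(vapply(xy, `[`, character(1), 1L)),
             y = as.integer(vapply(xy, `[`, character(1), 2L)),
             uid = hi$uid, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a run's truth table as TSV
#'
#' @param truth Truth data frame of a `sim_run`.
#' @param path File path.
#' @return `read_truth_table` returns the data frame.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
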