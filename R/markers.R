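# Marker sequences and file IO.
#
# A collection of identified marker sequences is held as a plain data.frame
# (class "marker_set") with columns sample_id, marker, origin, sex, sequence.
# FASTA headers follow the convention "sample_id|marker|origin[|sex]";
# fields beyond sample_id are optional and default to OTHER / NA.

MARKERS <- c("TROSPA", "S16", "COI", "ITS2", "CALR")
ORIGINS <- c("CZ", "ALG", "SYNTH", "OTHER")
SEXES   <- c("F", "M")

#' Build a marker-sequence collection
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param sequence Character vector of sequences over the IUPAC alphabet
#'   (gaps allowed; lowercase soft-mask is uppercased).
#' @param marker One of TROSPA, S16, COI, ITS2, CALR (recycled).
#' @param origin One of CZ, ALG, SYNTH, OTHER (recycled).
#' @param sex Optional "F"/"M" (recycled); NA when unknown.
#' @return A `marker_set` data.frame.
#' @export
marker_set <- function(sample_id, sequence, marker = "TROSPA",
                       origin = "SYNTH", sex = NA_character_) {
  n <- length(sample_id)
  stopifnot(length(sequence) == n)
  marker <- rep_len(as.character(marker), n)
  origin <- rep_len(as.character(origin), n)
  sex <- rep_len(as.character(sex), n)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id within collection: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(marker %in% MARKERS)) stop("unknown marker", call. = FALSE)
  if (!all(origin %in% ORIGINS)) stop("unknown origin", call. = FALSE)
  if (!all(is.na(sex) | sex %in% SEXES)) stop("sex must be F/M/NA", call. = FALSE)
  sequence <- toupper(sequence)
  for (i in seq_len(n)) {
    check_iupac_sequence(sequence[i], context = sample_id[i])
  }
  out <- data.frame(sample_id = as.character(sample_id), marker = marker,
                    origin = origin, sex = sex, sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_set", "data.frame")
  out
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d sequence(s); markers: %s\n", nrow(x),
              paste(unique(x$marker), collapse = ", ")))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    show$sequence <- paste0(substr(show$sequence, 1, 24),
                            ifelse(nchar(show$sequence) > 24, "...", ""))
    print.data.frame(show, row.names = FALSE)
    if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more\n")
  }
  invisible(x)
}

.parse_fasta_header <- function(header, lineno = NA) {
  fields <- strsplit(header, "|", fixed = TRUE)[[1]]
  fields <- trimws(fields)
  if (length(fields) < 1L || !nzchar(fields[1])) {
    stop("malformed FASTA header at line ", lineno, ": '>", header, "'",
         call. = FALSE)
  }
  marker <- if (length(fields) >= 2L && nzchar(fields[2])) fields[2] else "TROSPA"
  origin <- if (length(fields) >= 3L && nzchar(fields[3])) fields[3] else "OTHER"
  sex <- if (length(fields) >= 4L && nzchar(fields[4])) fields[4] else NA_character_
  if (!marker %in% MARKERS) {
    stop("malformed FASTA header at line ", lineno, ": unknown marker '",
         marker, "'", call. = FALSE)
  }
  list(sample_id = fields[1], marker = marker, origin = origin, sex = sex)
}

#' Read marker sequences from FASTA
#'
#' Headers are parsed as `sample_id|marker|origin[|sex]`; missing metadata
#' fields default to marker TROSPA / origin OTHER / sex NA. Sequences are
#' uppercased on ingest (lowercase is treated as soft-mask) and validated
#' against the IUPAC alphabet.
#'
#' @param path FASTA file path.
#' @return A [marker_set()] data.frame (possibly empty, with a warning).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(marker_set(character(), character()))
  }
  # line numbers of headers, for parse errors
  headers <- names(set)
  lines <- readLines(path, warn = FALSE)
  header_lines <- grep("^>", lines)
  meta <- lapply(seq_along(headers), function(i) {
    .parse_fasta_header(headers[i],
                        lineno = if (i <= length(header_lines)) header_lines[i] else NA)
  })
  seqs <- toupper(as.character(set))
  if (any(grepl("[a-z]", as.character(set)))) {
    message("soft-masked (lowercase) bases uppercased on ingest: ", path)
  }
  marker_set(sample_id = vapply(meta, `[[`, "", "sample_id"),
             sequence = unname(seqs),
             marker = vapply(meta, `[[`, "", "marker"),
             origin = vapply(meta, `[[`, "", "origin"),
             sex = vapply(meta, function(m) m$sex, ""))
}

#' Write marker sequences to FASTA
#'
#' Headers follow `sample_id|marker|origin[|sex]` (sex omitted when NA);
#' sequences are wrapped at 60 columns so write/read round-trips are
#' byte-stable.
#'
#' @param seqs A `marker_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  hdr <- ifelse(is.na(seqs$sex),
                paste(seqs$sample_id, seqs$marker, seqs$origin, sep = "|"),
                paste(seqs$sample_id, seqs$marker, seqs$origin, seqs$sex,
                      sep = "|"))
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read/write a TSV table
#'
#' Thin wrappers fixing the dialect used throughout the package: tab-separated,
#' header row, UTF-8, no quoting, no row names.
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' @param x A data.frame.
#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
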