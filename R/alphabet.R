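#' Amino acid residue symbols
#'
#' The 20 standard amino acids plus the UniProt placeholder symbols
#' U (selenocysteine), O (pyrrolysine), B (Asx), Z (Glx) and X (unknown),
#' in the fixed order used throughout the package.
#'
#' @return Character vector of 25 residue symbols.
#' @export
#' @examples
#' aa_residues()
aa_residues <- function() {
  c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
    "U", "O", "B", "Z", "X"
  )
}

#' Build a residue alphabet with a dedicated pad symbol
#'
#' An alphabet fixes the symbol-to-row mapping of the one-hot encoding.
#' The pad symbol always receives index 0 (the first one-hot row); the
#' residues receive indices 1..n in the order given.
#'
#' @param residues Ordered character vector of residue symbols (unique,
#'   single characters). Defaults to [aa_residues()].
#' @param pad Single pad character, not a member of `residues`. Default `"0"`.
#' @return An object of class `seqpad_alphabet`: a list with `symbols`
#'   (pad first, then residues), `pad`, `n` (number of residue symbols) and
#'   `index` (named integer vector mapping symbol to 0-based index).
#' @export
#' @examples
#' ab <- build_alphabet(c("A", "C", "D"), "0")
#' ab$n
#' ab$index
build_alphabet <- function(residues = aa_residues(), pad = "0") {
  stopifnot(is.character(residues), length(residues) >= 1, is.character(pad), length(pad) == 1)
  if (any(nchar(residues) != 1) || nchar(pad) != 1) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  if (anyDuplicated(residues)) {
    stop(
      "duplicate residue symbols: ",
      paste(unique(residues[duplicated(residues)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (pad %in% residues) {
    stop("pad symbol '", pad, "' collides with a residue symbol", call. = FALSE)
  }
  symbols <- c(pad, residues)
  index <- stats::setNames(seq_along(symbols) - 1L, symbols)
  structure(
    list(symbols = symbols, pad = pad, n = length(residues), index = index),
    class = "seqpad_alphabet"
  )
}

#' @export
print.seqpad_alphabet <- function(x, ...) {
  cat(
    "<seqpad_alphabet> n =", x$n, "residues + pad '", x$pad, "'\n ",
    paste(x$symbols, collapse = " "), "\n"
  )
  invisible(x)
}

# integer codes 1..n+1 (1 = pad) for a vector of padded symbol strings,
# all of equal length; rows are sequences
symbols_to_codes <- function(seqs, alphabet) {
  stopifnot(inherits(alphabet, "seqpad_alphabet"))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    stop("sequences must share a common length, got lengths ",
      paste(unique(lens), collapse = ", "),
      call. = FALSE
    )
  }
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE
  )
  codes <- matrix(match(chars, alphabet$symbols), nrow = nrow(chars))
  if (anyNA(codes)) {
    bad <- which(is.na(codes), arr.ind = TRUE)[1, ]
    stop(
      "unknown character '", chars[bad[1], bad[2]], "' at position ", bad[2],
      " of sequence ", bad[1],
      call. = FALSE
    )
  }
  codes
}

#' One-hot encode a padded sequence
#'
#' Encodes a fixed-length symbol string (residues plus pad characters) as a
#' binary matrix of shape (n+1) x T: one row per alphabet symbol (pad row
#' first), one column per position, exactly one 1 per column. With
#' `pad_row = FALSE` pad positions are instead encoded as all-zero columns
#' (the shape is unchanged; the pad row is simply never active).
#'
#' @param seq A symbol string of length T over the alphabet (pad included).
#' @param alphabet A [build_alphabet()] object.
#' @param pad_row Should pad positions activate the dedicated pad row
#'   (default `TRUE`) rather than be all-zero columns?
#' @return Binary matrix of dimension `(alphabet$n + 1) x nchar(seq)` with
#'   the alphabet symbols as rownames.
#' @export
#' @examples
#' ab <- build_alphabet(c("A", "C", "D"))
#' encode_one_hot("AC0", ab)
encode_one_hot <- function(seq, alphabet, pad_row = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1)
  codes <- drop(symbols_to_codes(seq, alphabet))
  T_len <- length(codes)
  m <- matrix(0L, nrow = alphabet$n + 1L, ncol = T_len,
    dimnames = list(alphabet$symbols, NULL)
  )
  active <- rep(TRUE, T_len)
  if (!pad_row) active <- codes != 1L
  m[cbind(codes[active], seq_len(T_len)[active])] <- 1L
  m
}

#' Decode a one-hot matrix back to a symbol string
#'
#' Inverse of [encode_one_hot()]. Under the default pad-row convention every
#' column must contain exactly one 1; with `pad_row = FALSE` an all-zero
#' column decodes to the pad symbol.
#'
#' @inheritParams encode_one_hot
#' @param matrix Binary matrix of shape (n+1) x T.
#' @return The decoded symbol string.
#' @export
#' @examples
#' ab <- build_alphabet(c("A", "C", "D"))
#' decode_one_hot(encode_one_hot("AC0", ab), ab)
decode_one_hot <- function(matrix, alphabet, pad_row = TRUE) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) != alphabet$n + 1L) {
    stop("matrix has ", nrow(matrix), " rows; alphabet implies ", alphabet$n + 1L, call. = FALSE)
  }
  sums <- colSums(matrix != 0)
  ok <- if (pad_row) sums == 1 else sums <= 1
  if (any(!ok)) {
    j <- which(!ok)[1]
    stop("malformed one-hot column ", j, ": ", sums[j], " active rows", call. = FALSE)
  }
  rows <- max.col(t(matrix), ties.method = "first")
  if (!pad_row) rows[sums == 0] <- 1L
  paste(alphabet$symbols[rows], collapse = "")
}

#' Read a FASTA file into a tibble
#'
#' Reads single- or multi-line FASTA records. Padded FASTA (bodies
#' containing the pad character) is accepted, so this reads both raw input
#' sequences and the output of [write_fasta()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first word of the header),
#'   `desc` (remainder of the header, `NA` if none) and `residues`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  tibble::tibble(
    id = unname(id), desc = unname(desc),
    residues = unname(as.character(set))
  )
}

#' Write sequences to FASTA
#'
#' @param data A data frame with columns `id` and `residues`, and optionally
#'   `desc` (appended to the header after a space).
#' @param path Output file path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(data)))
  headers <- data$id
  if ("desc" %in% names(data)) {
    has <- !is.na(data$desc) & nzchar(data$desc)
    headers[has] <- paste(headers[has], data$desc[has])
  }
  set <- Biostrings::BStringSet(stats::setNames(data$residues, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a one-hot matrix as a dense binary array with a JSON sidecar
#'
#' The matrix is stored column-major as unsigned bytes at `path`; the
#' sidecar `<path>.json` records the alphabet order, the common length T,
#' and the orientation (`"symbols x positions"`) so the array is
#' self-describing.
#'
#' @param matrix A one-hot matrix from [encode_one_hot()].
#' @param alphabet The alphabet it was encoded with.
#' @param path Output path for the binary array.
#' @return `path`, invisibly.
#' @export
write_one_hot <- function(matrix, alphabet, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(matrix), con)
  meta <- list(
    symbols = alphabet$symbols,
    pad = alphabet$pad,
    n_rows = nrow(matrix),
    T = ncol(matrix),
    orientation = "symbols x positions",
    storage = "uint8 column-major"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a one-hot matrix written by [write_one_hot()]
#'
#' @param path Path to the binary array (the sidecar `<path>.json` must
#'   exist alongside).
#' @return The one-hot matrix with symbol rownames.
#' @export
read_one_hot <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw <- readBin(path, what = "raw", n = meta$n_rows * meta$T)
  matrix(as.integer(raw),
    nrow = meta$n_rows, ncol = meta$T,
    dimnames = list(meta$symbols, NULL)
  )
}
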