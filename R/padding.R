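#' Padding mode names
#'
#' The seven single padding strategies. `"aug"` (augmentation: represent a
#' sequence by all seven) is accepted by the higher-level functions but is
#' not itself a placement rule.
#'
#' @return Character vector `c("post","pre","mid","ext","strf","rnd","zoom")`.
#' @export
pad_modes <- function() c("post", "pre", "mid", "ext", "strf", "rnd", "zoom")

#' Classify a padding mode as dense, sparse or augmented
#'
#' Dense paddings keep the pad symbols in one contiguous block (post-, pre-,
#' ext-, mid-); sparse paddings intersperse them (strf-, rnd-) or duplicate
#' residues instead (zoom-); `aug` is the augmentation scheme.
#'
#' @param mode A padding mode name.
#' @return `"dense"`, `"sparse"` or `"augmented"`.
#' @export
#' @examples
#' pad_mode_class("post")
#' pad_mode_class("strf")
pad_mode_class <- function(mode) {
  stopifnot(is.character(mode))
  out <- character(length(mode))
  out[mode %in% c("post", "pre", "ext", "mid")] <- "dense"
  out[mode %in% c("strf", "rnd", "zoom")] <- "sparse"
  out[mode == "aug"] <- "augmented"
  if (any(out == "")) {
    stop("unknown padding mode: ", paste(mode[out == ""], collapse = ", "), call. = FALSE)
  }
  out
}

# stable 31-bit string hash, for deriving per-sequence RNG streams
hash_id <- function(id) {
  vapply(id, function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# derive a per-sequence seed below 2^31 from (global seed, id)
derive_seed <- function(seed, id) {
  as.integer((abs(seed) + hash_id(id)) %% 2147483629 + 1)
}

# 1-based target positions of the L residues within 1..T, per mode.
# For zoom, returns the length-T monotone map of 1-based source indices.
pad_positions <- function(L, T_len, mode, seed = 1L) {
  Z <- T_len - L
  switch(mode,
    post = seq_len(L),
    pre = Z + seq_len(L),
    mid = {
      left <- ceiling(L / 2)
      c(seq_len(left), (T_len - (L - left) + 1L) + seq_len(L - left) - 1L)
    },
    ext = {
      lead <- floor(Z / 2)
      lead + seq_len(L)
    },
    strf = floor((seq_len(L) - 1) * T_len / L) + 1L,
    rnd = withr::with_seed(seed, sort(sample.int(T_len, L))),
    zoom = floor((seq_len(T_len) - 1) * L / T_len) + 1L,
    stop("unknown padding mode: ", mode, call. = FALSE)
  )
}

#' Pad a single residue sequence to a common length
#'
#' Places the L residues of `seq` into a string of length `length` using the
#' chosen strategy, filling the remaining positions with the pad symbol.
#' `zoom` instead resamples the sequence (contiguous residues repeated) so
#' the output contains no pad symbols. All modes are deterministic given
#' their inputs; `rnd` draws its pad positions from a stream derived from
#' `(seed, id)` so re-runs and augmentation are stable.
#'
#' @param seq Residue string of length L <= `length`, not containing `pad`.
#' @param length Target common length T (paper-scale default 1000).
#' @param mode One of [pad_modes()].
#' @param pad Pad character, default `"0"`.
#' @param seed Integer seed; used by `rnd` only.
#' @param id Optional sequence identifier mixed into the `rnd` stream.
#' @return A list of class `seqpad_padded`: `symbols` (the padded string),
#'   `source_id`, `L`, `mode`, and `residue_positions` (1-based positions of
#'   the original residues; for `zoom`, the monotone source-index map of
#'   length T).
#' @export
#' @examples
#' pad_sequence("ABCD", 7, "post", pad = "0")$symbols # "ABCD000"
#' pad_sequence("ABCD", 7, "strf")$symbols # "AB0C0D0"
#' pad_sequence("ABCD", 7, "zoom")$symbols # "AABBCCD"
pad_sequence <- function(seq, length, mode = pad_modes(), pad = "0",
                         seed = 1L, id = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(seq), base::length(seq) == 1, length >= 1)
  L <- nchar(seq)
  if (L > length) {
    stop("sequence of length ", L, " exceeds target length ", length,
      "; truncate or filter first",
      call. = FALSE
    )
  }
  if (grepl(pad, seq, fixed = TRUE)) {
    stop("sequence already contains the pad symbol '", pad, "'", call. = FALSE)
  }
  if (L == 0 && mode == "zoom" && length > 0) {
    stop("cannot zoom-pad an empty sequence to length ", length, call. = FALSE)
  }
  rnd_seed <- if (is.null(id)) derive_seed(seed, "") else derive_seed(seed, id)
  pos <- pad_positions(L, length, mode, seed = rnd_seed)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (mode == "zoom") {
    symbols <- paste(chars[pos], collapse = "")
  } else {
    out <- rep(pad, length)
    out[pos] <- chars
    symbols <- paste(out, collapse = "")
  }
  structure(
    list(
      symbols = symbols, source_id = if (is.null(id)) NA_character_ else id,
      L = L, mode = mode, residue_positions = as.integer(pos)
    ),
    class = "seqpad_padded"
  )
}

#' @export
print.seqpad_padded <- function(x, ...) {
  cat("<seqpad_padded> mode =", x$mode, " L =", x$L, " T =", nchar(x$symbols), "\n ")
  cat(substr(x$symbols, 1, 70), if (nchar(x$symbols) > 70) "...", "\n")
  invisible(x)
}

#' Truncate a residue sequence to at most T residues
#'
#' `side = "tail"` (the default) cuts the tail, keeping the first T
#' residues; `side = "head"` cuts the head, keeping the last T.
#'
#' @param seq Residue string.
#' @param length Maximum length T.
#' @param side Which end to cut: `"tail"` or `"head"`.
#' @return The (possibly shortened) residue string.
#' @export
#' @examples
#' truncate_sequence("ABCDEFGHIJ", 7) # "ABCDEFG"
truncate_sequence <- function(seq, length, side = c("tail", "head")) {
  side <- match.arg(side)
  L <- nchar(seq)
  if (L <= length) {
    return(seq)
  }
  if (side == "tail") substr(seq, 1L, length) else substr(seq, L - length + 1L, L)
}

#' Represent one sequence by all seven padding strategies
#'
#' The augmentation scheme: each sequence is expanded into its seven
#' single-mode paddings, each identical to the corresponding
#' [pad_sequence()] output under the same seed.
#'
#' @inheritParams pad_sequence
#' @return A named list of seven `seqpad_padded` objects, one per mode.
#' @export
augment_sequence <- function(seq, length, pad = "0", seed = 1L, id = NULL) {
  stats::setNames(
    lapply(pad_modes(), function(m) {
      pad_sequence(seq, length, m, pad = pad, seed = seed, id = id)
    }),
    pad_modes()
  )
}

#' Pad a table of sequences
#'
#' Tibble-first interface over [pad_sequence()] / [augment_sequence()].
#' With `mode = "aug"` each input row expands to seven output rows, one per
#' single mode, sharing the input `id`.
#'
#' @param data Data frame with columns `id` and `residues` (other columns
#'   are carried through).
#' @param length Target common length T.
#' @param mode A single mode among [pad_modes()] or `"aug"`.
#' @param pad Pad character.
#' @param seed Integer seed for the `rnd` stream.
#' @return A tibble with the input columns (minus `residues`) plus
#'   `padding` (the mode), `padded` (the length-T string), `original_length`
#'   and `residue_positions` (list column).
#' @export
#' @examples
#' d <- tibble::tibble(id = c("s1", "s2"), residues = c("ACDE", "AC"))
#' pad_sequences(d, length = 6, mode = "strf")
pad_sequences <- function(data, length, mode = "post", pad = "0", seed = 1L) {
  stopifnot(all(c("id", "residues") %in% names(data)), base::length(mode) == 1)
  modes <- if (mode == "aug") pad_modes() else match.arg(mode, pad_modes())
  meta <- dplyr::select(data, -"residues")
  out <- purrr::map(modes, function(m) {
    padded_objs <- purrr::map2(data$residues, data$id, function(s, i) {
      pad_sequence(s, length, m, pad = pad, seed = seed, id = i)
    })
    dplyr::bind_cols(
      meta,
      tibble::tibble(
        padding = m,
        padded = purrr::map_chr(padded_objs, "symbols"),
        original_length = purrr::map_int(padded_objs, function(p) as.integer(p$L)),
        residue_positions = purrr::map(padded_objs, "residue_positions")
      )
    )
  })
  dplyr::bind_rows(out)
}
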