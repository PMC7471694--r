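#' Load sequences and EC annotations
#'
#' Joins a FASTA file of amino acid sequences with a TSV annotation table
#' (`id<TAB>ec1;ec2;...`, no header; an empty second field means
#' non-enzyme). Sequences absent from the TSV get an empty EC list. Every
#' EC string must have four dot-separated fields with a first digit in 1-7.
#'
#' @param fasta Path to the FASTA file.
#' @param tsv Path to the annotation TSV.
#' @return A tibble with columns `id`, `residues` and `ec` (list column of
#'   character vectors, possibly empty).
#' @export
load_annotations <- function(fasta, tsv) {
  seqs <- read_fasta(fasta)
  if (anyDuplicated(seqs$id)) {
    stop("duplicate sequence ids in FASTA: ",
      paste(unique(seqs$id[duplicated(seqs$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  ann <- readr::read_tsv(tsv,
    col_names = c("id", "ec"), col_types = "cc",
    na = character(), progress = FALSE
  )
  if (anyDuplicated(ann$id)) {
    stop("duplicate ids in annotation TSV", call. = FALSE)
  }
  missing <- setdiff(ann$id, seqs$id)
  if (length(missing) > 0) {
    stop("annotated ids missing from FASTA: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  ec_list <- stats::setNames(
    lapply(ann$ec, function(x) {
      if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
    }),
    ann$id
  )
  for (ecs in ec_list) {
    for (e in ecs) validate_ec(e)
  }
  tibble::tibble(
    id = seqs$id,
    residues = seqs$residues,
    ec = lapply(seqs$id, function(i) ec_list[[i]] %||% character(0))
  )
}

validate_ec <- function(ec) {
  fields <- strsplit(ec, ".", fixed = TRUE)[[1]]
  first <- suppressWarnings(as.integer(fields[1]))
  if (length(fields) != 4 || is.na(first) || first < 1 || first > 7) {
    stop("malformed EC number '", ec,
      "': expected 4 dot-separated fields with first digit 1-7",
      call. = FALSE
    )
  }
  invisible(ec)
}

#' Drop sequences longer than a threshold
#'
#' Keeps records whose residue length is at most `max_len` (inclusive) and
#' reports how many were discarded.
#'
#' @param records A data frame with a `residues` column.
#' @param max_len Length threshold, default 1000 residues.
#' @return The filtered tibble.
#' @export
filter_by_length <- function(records, max_len = 1000L) {
  keep <- nchar(records$residues) <= max_len
  if (any(!keep)) {
    message("filter_by_length: discarded ", sum(!keep), " of ", length(keep),
      " records longer than ", max_len, " residues")
  }
  tibble::as_tibble(records[keep, , drop = FALSE])
}

#' Expand multi-EC records into per-class labelled samples
#'
#' Each record yields one sample per distinct first EC digit (duplicated
#' first digits collapse); records without EC annotation yield one
#' non-enzyme sample. Expanded samples share `origin_id` so splits can keep
#' them together.
#'
#' @param records Output of [load_annotations()] (columns `id`, `residues`,
#'   `ec`).
#' @return A tibble of labelled samples: `id`, `origin_id`, `residues`,
#'   `task1_label` (0 non-enzyme / 1 enzyme) and `task2_label` (enzyme class
#'   1-7, `NA` for non-enzymes).
#' @export
expand_multi_ec <- function(records) {
  rows <- purrr::pmap(
    list(records$id, records$residues, records$ec),
    function(id, residues, ec) {
      digits <- sort(unique(as.integer(substr(ec, 1, regexpr(".", ec, fixed = TRUE) - 1))))
      if (length(digits) == 0) {
        tibble::tibble(
          id = id, origin_id = id, residues = residues,
          task1_label = 0L, task2_label = NA_integer_
        )
      } else {
        orig <- id
        new_id <- if (length(digits) > 1) paste0(orig, "|ec", digits) else orig
        tibble::tibble(
          id = new_id, origin_id = orig, residues = residues,
          task1_label = 1L, task2_label = digits
        )
      }
    }
  )
  dplyr::bind_rows(rows)
}

#' Assign samples to train/validation/test parts, repeatedly
#'
#' Random 70/15/15 splits (by default), repeated `n_repeats` times with
#' seed-derived streams. Assignment is grouped by `origin_id`: all expanded
#' duplicates of a record land in the same part, so no sequence leaks
#' across partitions. Each part's sample count is realised to within one
#' sample (up to the largest origin group minus one when a group straddles
#' a boundary). With `stratify = TRUE` the procedure is applied within each
#' label stratum.
#'
#' @param samples Output of [expand_multi_ec()] (needs `id`, `origin_id`;
#'   `task1_label`/`task2_label` only for `stratify`).
#' @param fractions Numeric length-3 vector summing to 1
#'   (train, validation, test).
#' @param n_repeats Number of independent split repetitions, default 10.
#' @param seed Integer seed.
#' @param stratify Stratify by label (task-2 class where present, else
#'   enzyme/non-enzyme)? Default `FALSE`: plain random splits.
#' @return A tibble with columns `fold` (1..n_repeats), `id` and `part`
#'   (`"train"`, `"val"` or `"test"`).
#' @export
make_splits <- function(samples, fractions = c(0.70, 0.15, 0.15),
                        n_repeats = 10L, seed = 1L, stratify = FALSE) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  if (nrow(samples) < 3) stop("need at least 3 samples to split", call. = FALSE)
  strata <- if (stratify) {
    lab <- if (!is.null(samples$task2_label)) {
      ifelse(is.na(samples$task2_label), "0", as.character(samples$task2_label))
    } else {
      as.character(samples$task1_label)
    }
    split(samples, lab)
  } else {
    list(samples)
  }
  out <- purrr::map(seq_len(n_repeats), function(r) {
    parts <- purrr::map(strata, function(s) {
      split_one(s, fractions, seed = derive_seed(seed, paste0("split", r)))
    })
    dplyr::bind_rows(parts) |> dplyr::mutate(fold = r, .before = 1)
  })
  dplyr::bind_rows(out)
}

# one grouped split of one stratum
split_one <- function(samples, fractions, seed) {
  origins <- samples |>
    dplyr::count(.data$origin_id, name = "size")
  origins <- withr::with_seed(seed, origins[sample.int(nrow(origins)), ])
  n <- sum(origins$size)
  cs <- cumsum(origins$size)
  t1 <- round(n * fractions[1])
  t2 <- round(n * (fractions[1] + fractions[2]))
  origins$part <- ifelse(cs <= t1, "train", ifelse(cs <= t2, "val", "test"))
  samples |>
    dplyr::inner_join(origins[, c("origin_id", "part")], by = "origin_id") |>
    dplyr::select("id", "part")
}

#' Write a split plan as CSV
#'
#' Serialises a [make_splits()] plan with the schema `repeat,id,part`.
#'
#' @param splits A split tibble from [make_splits()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_splits_csv <- function(splits, path) {
  out <- dplyr::rename(splits, "repeat" = "fold")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
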