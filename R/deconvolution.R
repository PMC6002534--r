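# Hairpin read deconvolution: flank location, loop/stem validation,
# mismatch-tolerant library matching, clone classification.
#
# All matching is substitution-only (Hamming). Amplicon reads of a fixed
# construct rarely carry indels, and any read shifted by one is caught by
# the ambiguity/threshold contracts rather than silently mis-assigned.

# Hamming distances of `pattern` (character scalar) against every read in
# `seqs` at every start offset. Returns an n_reads x n_offsets integer
# matrix; reads must share one length.
slide_mismatch <- function(seqs, pattern) {
  M <- seq_char_matrix(seqs)
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  m <- length(p)
  L <- ncol(M)
  n_off <- L - m + 1L
  if (n_off < 1L) return(matrix(NA_integer_, nrow(M), 0L))
  out <- matrix(0L, nrow(M), n_off)
  for (k in seq_len(n_off)) {
    block <- M[, k:(k + m - 1L), drop = FALSE]
    out[, k] <- as.integer(rowSums(block != rep(p, each = nrow(M))))
  }
  out
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# Best placement per read: list(dist, offset, unique). Ties in the minimum
# distance mark the read ambiguous.
best_offset <- function(dist_mat, search_from = NULL) {
  n <- nrow(dist_mat)
  res_d <- integer(n); res_o <- integer(n); uniq <- logical(n)
  for (i in seq_len(n)) {
    row <- dist_mat[i, ]
    if (!is.null(search_from)) {
      from <- search_from[i]
      if (from > length(row)) {
        res_d[i] <- NA_integer_; res_o[i] <- NA_integer_; uniq[i] <- FALSE
        next
      }
      row[seq_len(from - 1L)] <- NA_integer_
    }
    d <- min(row, na.rm = TRUE)
    w <- which(row == d)
    res_d[i] <- d; res_o[i] <- w[1L]; uniq[i] <- length(w) == 1L
  }
  list(dist = res_d, offset = res_o, unique = uniq)
}

#' Locate the hairpin insert between the vector flanks
#'
#' Finds the best Hamming-distance placement of the 5' flank and then of
#' the 3' flank downstream of it, in both the read and its reverse
#' complement; the orientation with fewer total flank mismatches wins.
#' Reads whose best placement exceeds `max_flank_mismatch`, or with tied
#' conflicting placements/orientations, fail as `no_flank`.
#'
#' @param reads Character vector of read sequences (or a tibble with a
#'   `sequence` column, e.g. from [read_reads()]).
#' @param flank5,flank3 Vector flank sequences bounding the insert.
#' @param max_flank_mismatch Per-flank mismatch tolerance (default 2).
#' @return A tibble: `sequence`, `insert` (`NA` on failure), `orientation`
#'   (`"fwd"`/`"rev"`), `flank_mismatches`, `located` (logical).
#' @export
locate_insert <- function(reads, flank5, flank3, max_flank_mismatch = 2) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  stopifnot(is.character(seqs), length(seqs) > 0)
  if (any(nchar(seqs) <= nchar(flank5) + nchar(flank3))) {
    abort("reads must be longer than the two flanks combined")
  }
  n <- length(seqs)
  out <- tibble::tibble(sequence = seqs, insert = NA_character_,
                        orientation = NA_character_,
                        flank_mismatches = NA_integer_, located = FALSE)
  # evaluate one orientation for a length-homogeneous group of reads
  eval_orient <- function(ss) {
    d5 <- best_offset(slide_mismatch(ss, flank5))
    from <- d5$offset + nchar(flank5)
    d3 <- best_offset(slide_mismatch(ss, flank3), search_from = from)
    total <- d5$dist + d3$dist
    ok <- d5$unique & d3$unique &
      d5$dist <= max_flank_mismatch & d3$dist <= max_flank_mismatch &
      !is.na(d3$offset) & (d3$offset > from)  # nonempty insert
    list(total = ifelse(ok, total, NA_integer_),
         start = from, end = d3$offset - 1L)
  }
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    ss <- seqs[idx]
    fwd <- eval_orient(ss)
    rc <- revcomp_chr(ss)
    rev <- eval_orient(rc)
    pick_fwd <- !is.na(fwd$total) & (is.na(rev$total) | fwd$total < rev$total)
    pick_rev <- !is.na(rev$total) & (is.na(fwd$total) | rev$total < fwd$total)
    # equal-score success in both orientations is ambiguous: neither picked
    ins <- rep(NA_character_, length(ss))
    ins[pick_fwd] <- substr(ss[pick_fwd], fwd$start[pick_fwd],
                            fwd$end[pick_fwd])
    ins[pick_rev] <- substr(rc[pick_rev], rev$start[pick_rev],
                            rev$end[pick_rev])
    out$insert[idx] <- ins
    out$orientation[idx] <- ifelse(pick_fwd, "fwd",
                                   ifelse(pick_rev, "rev", NA))
    out$flank_mismatches[idx] <- ifelse(pick_fwd, fwd$total,
                                        ifelse(pick_rev, rev$total, NA))
    out$located[idx] <- pick_fwd | pick_rev
  }
  out
}

#' Validate the hairpin structure of an insert
#'
#' Locates the expected loop inside the insert (best Hamming placement;
#' ties broken toward balanced arms), checks the loop against its
#' tolerance, then checks stem complementarity: the loop-proximal arms
#' must reverse-complement each other within `max_stem_mismatch`. On pass,
#' the 5' (sense) arm is returned.
#'
#' @param inserts Character vector of insert sequences (`NA` allowed).
#' @param expected_loop The construct loop sequence.
#' @param max_loop_mismatch,max_stem_mismatch Tolerances (defaults 0, the
#'   stringent-filtering setting). G:U wobble is not accepted (DNA-level
#'   reads); set `max_stem_mismatch` instead if a laxer stem is wanted.
#' @return A tibble: `insert`, `status` (`"pass"`, `"fail_loop"`,
#'   `"fail_stem"`), `sense` (on pass), `loop_mismatches`,
#'   `stem_mismatches`.
#' @export
validate_hairpin <- function(inserts, expected_loop,
                             max_loop_mismatch = 0, max_stem_mismatch = 0) {
  stopifnot(is.character(inserts))
  ll <- nchar(expected_loop)
  n <- length(inserts)
  out <- tibble::tibble(insert = inserts, status = NA_character_,
                        sense = NA_character_,
                        loop_mismatches = NA_integer_,
                        stem_mismatches = NA_integer_)
  todo <- which(!is.na(inserts))
  # pass 1: loop placement per insert (grouped by length for the slider)
  arm_idx <- integer(0); arm1s <- character(0); arm2s <- character(0)
  for (L in unique(nchar(inserts[todo]))) {
    idx <- todo[nchar(inserts[todo]) == L]
    if (L < ll + 2L) {
      out$status[idx] <- "fail_loop"
      next
    }
    dm <- slide_mismatch(inserts[idx], expected_loop)
    for (j in seq_along(idx)) {
      i <- idx[j]
      row <- dm[j, ]
      d <- min(row)
      cand <- which(row == d)
      # balanced-arm tie-break: placement closest to the insert center
      centers <- abs((cand - 1L) - (L - ll - (cand - 1L)))
      k <- cand[which.min(centers)]
      out$loop_mismatches[i] <- d
      if (d > max_loop_mismatch) {
        out$status[i] <- "fail_loop"
        next
      }
      arm1 <- substr(inserts[i], 1L, k - 1L)
      arm2 <- substr(inserts[i], k + ll, L)
      m <- min(nchar(arm1), nchar(arm2))
      if (m < 1L) {
        out$status[i] <- "fail_stem"
        next
      }
      arm_idx <- c(arm_idx, i)
      arm1s <- c(arm1s, arm1)
      arm2s <- c(arm2s, arm2)
    }
  }
  # pass 2: stem complementarity, vectorized over all candidates
  if (length(arm_idx)) {
    m <- pmin(nchar(arm1s), nchar(arm2s))
    a1 <- substr(arm1s, nchar(arm1s) - m + 1L, nchar(arm1s))
    a2rc <- revcomp_chr(substr(arm2s, 1L, m))
    sm <- hamming(a1, a2rc)
    out$stem_mismatches[arm_idx] <- sm
    ok <- sm <= max_stem_mismatch
    out$status[arm_idx] <- ifelse(ok, "pass", "fail_stem")
    out$sense[arm_idx[ok]] <- arm1s[ok]
  }
  out
}

#' Match a sense arm to the shRNA library
#'
#' Minimum-Hamming match against the library sense sequences; unequal
#' lengths are compared by sliding the shorter within the longer. A match
#' requires a unique best record within `max_mismatch`; ties are ambiguous
#' and fail.
#'
#' @param senses Character vector of sense sequences (`NA` allowed).
#' @param library Library tibble with `shrna_id` and `sense`.
#' @param max_mismatch Tolerance (default 2).
#' @return A tibble: `sense`, `shrna_id` (`NA` on failure), `mismatches`,
#'   `matched` (logical).
#' @export
match_library <- function(senses, library, max_mismatch = 2) {
  if (!is.data.frame(library) || nrow(library) == 0) abort("empty library")
  stopifnot(is.character(senses))
  lib <- library$sense
  uq <- unique(senses[!is.na(senses)])
  res <- lapply(uq, function(s) {
    d <- vapply(lib, function(l) {
      if (nchar(s) == nchar(l)) return(hamming(s, l))
      short <- if (nchar(s) < nchar(l)) s else l
      long <- if (nchar(s) < nchar(l)) l else s
      offs <- seq_len(nchar(long) - nchar(short) + 1L)
      min(vapply(offs, function(k) {
        hamming(short, substr(long, k, k + nchar(short) - 1L))
      }, 0L))
    }, 0L, USE.NAMES = FALSE)
    dmin <- min(d)
    hits <- which(d == dmin)
    if (dmin <= max_mismatch && length(hits) == 1L) {
      list(id = library$shrna_id[hits], mm = dmin, ok = TRUE)
    } else {
      list(id = NA_character_, mm = dmin, ok = FALSE)
    }
  })
  lut_id <- setNames(vapply(res, `[[`, "", "id"), uq)
  lut_mm <- setNames(vapply(res, `[[`, 0L, "mm"), uq)
  lut_ok <- setNames(vapply(res, `[[`, TRUE, "ok"), uq)
  tibble::tibble(sense = senses,
                 shrna_id = unname(lut_id[senses]),
                 mismatches = unname(lut_mm[senses]),
                 matched = !is.na(senses) & unname(lut_ok[senses]) %in% TRUE)
}

#' Call shRNA identity for every read
#'
#' Full deconvolution pipeline: flank location ([locate_insert()]),
#' loop/stem validation ([validate_hairpin()]), and library matching
#' ([match_library()]). Flank and loop sequences are taken from the
#' library table and must be shared by all records.
#'
#' @param reads Character vector of sequences or a tibble with `read_id`
#'   and `sequence` (e.g. [read_reads()] or [simulate_hairpin_reads()]).
#' @param library Library tibble (`shrna_id`, `sense`, `loop`, `flank5`,
#'   `flank3`).
#' @param max_flank_mismatch,max_loop_mismatch,max_stem_mismatch,max_library_mismatch
#'   Stage tolerances (defaults 2, 0, 0, 2 — the stringent-filtering
#'   settings, all exposed).
#' @return A read-call tibble: `read_id`, `status` (`"pass"`,
#'   `"fail_no_flank"`, `"fail_loop"`, `"fail_stem"`,
#'   `"fail_no_match"`), `matched_shrna_id`, `mismatches` (library
#'   mismatches of the matched sense), `orientation`.
#' @export
call_reads <- function(reads, library,
                       max_flank_mismatch = 2, max_loop_mismatch = 0,
                       max_stem_mismatch = 0, max_library_mismatch = 2) {
  if (!is.data.frame(library) || nrow(library) == 0) abort("empty library")
  for (col in c("loop", "flank5", "flank3")) {
    if (length(unique(library[[col]])) != 1L) {
      abort(sprintf("library records disagree on `%s`; one construct scaffold expected", col))
    }
  }
  ids <- if (is.data.frame(reads) && "read_id" %in% names(reads))
    reads$read_id else sprintf("read%06d", seq_along(
      if (is.data.frame(reads)) reads$sequence else reads))
  seqs <- if (is.data.frame(reads)) reads$sequence else reads

  # deduplicate identical sequences; the pipeline is sequence-deterministic
  uq <- unique(seqs)
  loc <- locate_insert(uq, library$flank5[1L], library$flank3[1L],
                       max_flank_mismatch)
  val <- validate_hairpin(loc$insert, library$loop[1L],
                          max_loop_mismatch, max_stem_mismatch)
  mat <- match_library(val$sense, library, max_library_mismatch)

  uq_status <- dplyr::case_when(
    !loc$located ~ "fail_no_flank",
    val$status == "fail_loop" ~ "fail_loop",
    val$status == "fail_stem" ~ "fail_stem",
    !mat$matched ~ "fail_no_match",
    TRUE ~ "pass")
  uq_id <- ifelse(uq_status == "pass", mat$shrna_id, NA_character_)
  uq_mm <- ifelse(uq_status == "pass", mat$mismatches, NA_integer_)
  lut <- match(seqs, uq)
  tibble::tibble(
    read_id = ids,
    status = uq_status[lut],
    matched_shrna_id = uq_id[lut],
    mismatches = uq_mm[lut],
    orientation = loc$orientation[lut])
}

#' Rank pass-read shRNA counts for a clone
#'
#' @param calls A read-call tibble from [call_reads()].
#' @return A tibble of pass-read counts per shRNA, ranked by descending
#'   abundance, with the fraction of pass reads.
#' @export
count_shrnas <- function(calls) {
  calls |>
    dplyr::filter(.data$status == "pass") |>
    dplyr::count(shrna_id = .data$matched_shrna_id, name = "reads",
                 sort = TRUE) |>
    dplyr::mutate(fraction = .data$reads / sum(.data$reads))
}

#' Summarize and classify a clone from its read calls
#'
#' Ranks pass-read shRNA counts and classifies the clone: `"none"` when
#' pass reads fall below `min_pass_reads`, `"single"` when the dominant
#' shRNA holds at least `single_dominance` of the pass reads, `"multiple"`
#' otherwise.
#'
#' @param calls A read-call tibble from [call_reads()].
#' @param clone_id Clone label for the summary row.
#' @param single_dominance Dominant-fraction threshold for a single-shRNA
#'   call (default 0.95).
#' @param min_pass_reads Minimum pass reads for any call (default 50).
#' @return A one-row tibble: `clone_id`, `total_reads`, `pass_reads`,
#'   `pass_fraction`, `n_shrnas`, `top_shrna`, `top_fraction`,
#'   `second_shrna`, `second_fraction`, `classification`. The ranked count
#'   table is attached as attribute `"counts"`.
#' @export
summarize_clone_calls <- function(calls, clone_id = "clone",
                                  single_dominance = 0.95,
                                  min_pass_reads = 50) {
  if (nrow(calls) == 0) abort("no read calls")
  counts <- count_shrnas(calls)
  n_pass <- sum(counts$reads)
  cls <- if (n_pass < min_pass_reads) "none"
    else if (counts$fraction[1L] >= single_dominance) "single"
    else "multiple"
  out <- tibble::tibble(
    clone_id = clone_id,
    total_reads = nrow(calls),
    pass_reads = n_pass,
    pass_fraction = n_pass / nrow(calls),
    n_shrnas = nrow(counts),
    top_shrna = if (nrow(counts)) counts$shrna_id[1L] else NA_character_,
    top_fraction = if (nrow(counts)) counts$fraction[1L] else NA_real_,
    second_shrna = if (nrow(counts) > 1) counts$shrna_id[2L] else NA_character_,
    second_fraction = if (nrow(counts) > 1) counts$fraction[2L] else NA_real_,
    classification = cls)
  structure(out, counts = counts)
}
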