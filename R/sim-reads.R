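#' A synthetic miR-30-style shRNA library table
#'
#' Builds a stand-in library of hairpin records with the structure of
#' miR-30-adapted shRNA constructs: a shared 5' flank, a unique sense
#' (passenger) arm per hairpin, a shared loop, and a shared 3' flank. The
#' flank and loop constants are the widely published miR-30 scaffold
#' context sequences; the sense arms are random and the gene symbols are
#' placeholders, so the table is synthetic and carries no real library
#' content.
#'
#' @param n Number of hairpins.
#' @param sense_length Sense-arm length in nt (typical miR-30 arms are
#'   19--22; default 22).
#' @param seed Optional seed for the random sense arms.
#' @return A tibble with columns `shrna_id`, `gene_symbol`, `sense`,
#'   `loop`, `flank5`, `flank3`.
#' @export
#' @examples
#' hairpin_library(3, seed = 1)
hairpin_library <- function(n = 10, sense_length = 22, seed = NULL) {
  n <- assert_count(n, "n")
  sense_length <- assert_count(sense_length, "sense_length", lower = 15)
  with_seed_maybe(seed, {
    sense <- character(0)
    while (length(unique(sense)) < n) {
      sense <- unique(c(sense, vapply(seq_len(n), function(i) {
        paste(sample(DNA_BASES, sense_length, replace = TRUE), collapse = "")
      }, character(1))))
    }
    tibble::tibble(
      shrna_id = sprintf("sh%04d", seq_len(n)),
      gene_symbol = sprintf("GENE%04d", seq_len(n)),
      sense = sense[seq_len(n)],
      loop = "TAGTGAAGCCACAGATGTA",
      flank5 = "TGCTGTTGACAGTGAGCG",
      flank3 = "TGCCTACTGCCTCGGA"
    )
  })
}

#' Simulate hairpin amplicon sequencing reads with ground truth
#'
#' Each clean read is `flank5 + sense + loop + revcomp(sense) + flank3` for
#' one library hairpin. Sequencing noise is substitution-only at a per-base
#' rate; a chosen fraction of reads additionally carries a planted defect:
#' either a single-base loop edit or a single-base edit in one stem arm
#' (breaking sense/antisense complementarity). The truth table records the
#' source hairpin, the planted defect, and the number of random
#' substitutions for every read.
#'
#' @param library A library tibble as from [hairpin_library()], optionally
#'   subset to the hairpins carried by the simulated clone. Relative
#'   abundances can be set via `reads_per_shrna` as a vector.
#' @param reads_per_shrna Reads per library record (scalar or one value
#'   per record).
#' @param substitution_rate Per-base substitution probability in `[0, 1]`.
#' @param corrupt_fraction Fraction of reads given a planted defect, in
#'   `[0, 1]`; defect type alternates between loop and stem edits.
#' @param seed Optional seed for exact reproducibility.
#' @return A tibble with one row per read: `read_id`, `sequence`,
#'   `shrna_id` (the true source), `defect` (`"none"`, `"loop"`,
#'   `"stem"`), `n_substitutions`.
#' @export
simulate_hairpin_reads <- function(library, reads_per_shrna = 1000,
                                   substitution_rate = 0.005,
                                   corrupt_fraction = 0, seed = NULL) {
  if (!is.data.frame(library) || nrow(library) == 0) {
    abort("`library` must be a nonempty library table")
  }
  need <- c("shrna_id", "sense", "loop", "flank5", "flank3")
  if (!all(need %in% names(library))) {
    abort(paste("`library` needs columns:", paste(need, collapse = ", ")))
  }
  assert_scalar_number(substitution_rate, "substitution_rate", 0, 1)
  assert_scalar_number(corrupt_fraction, "corrupt_fraction", 0, 1)
  counts <- rep_len(as.integer(reads_per_shrna), nrow(library))
  if (any(counts < 0)) abort("`reads_per_shrna` must be non-negative")

  with_seed_maybe(seed, {
    clean <- paste0(library$flank5, library$sense, library$loop,
                    revcomp_chr(library$sense), library$flank3)
    src <- rep(seq_len(nrow(library)), counts)
    n <- length(src)
    if (n == 0) abort("no reads requested")
    seqs <- clean[src]

    # Random substitutions: binomial count per read, positions uniform.
    L <- nchar(seqs)
    nsub <- rbinom(n, L, substitution_rate)
    for (i in which(nsub > 0)) {
      for (p in sample.int(L[i], nsub[i])) {
        b <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(DNA_BASES[DNA_BASES != b], 1L)
      }
    }

    # Planted defects on a sampled fraction, alternating loop/stem edits.
    defect <- rep("none", n)
    n_bad <- round(corrupt_fraction * n)
    if (n_bad > 0) {
      bad <- sample.int(n, n_bad)
      kind <- rep_len(c("loop", "stem"), n_bad)
      f5 <- nchar(library$flank5)[src[bad]]
      sl <- nchar(library$sense)[src[bad]]
      ll <- nchar(library$loop)[src[bad]]
      for (j in seq_along(bad)) {
        i <- bad[j]
        if (kind[j] == "loop") {
          pos <- f5[j] + sl[j] + sample.int(ll[j], 1L)
        } else {
          # one arm only: sense or antisense, never both
          arm_start <- if (runif(1) < 0.5) f5[j] else f5[j] + sl[j] + ll[j]
          pos <- arm_start + sample.int(sl[j], 1L)
        }
        b <- substr(seqs[i], pos, pos)
        substr(seqs[i], pos, pos) <- sample(setdiff(DNA_BASES, b), 1L)
        defect[i] <- kind[j]
      }
    }

    tibble::tibble(
      read_id = sprintf("read%06d", seq_len(n)),
      sequence = seqs,
      shrna_id = library$shrna_id[src],
      defect = defect,
      n_substitutions = nsub
    )
  })
}

#' Write simulated reads as FASTQ
#'
#' Flat Sanger quality (`I`, Q40) for every base.
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  quals <- Biostrings::PhredQuality(strrep("I", nchar(reads$sequence)))
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' @param path Input file (gzip allowed); format chosen by extension.
#' @return A tibble with `read_id` and `sequence`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE))
    "fasta" else "fastq"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(read_id = sub(" .*", "", names(x)),
                 sequence = unname(as.character(x)))
}
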