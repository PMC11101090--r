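## MinHash sketching, Mash distance, and the distance-keyed aligner and
## parameter recommendation rules.

#' Sketch a sequence set with bottom-s MinHash
#'
#' Hashes every canonical k-mer (the minimum of a k-mer and its reverse
#' complement, 2-bit encoded) with a fixed-seed 64-bit mix and keeps the
#' `s` smallest distinct values. k-mers containing non-ACGT characters are
#' skipped.
#'
#' @param seqs a `DNAStringSet`, or a character vector of sequences.
#' @param k k-mer size (default 21).
#' @param s sketch size (default 1000).
#' @return A [Sketch-class].
#' @examples
#' sketchSequences(paste(rep("ACGTTGCA", 20), collapse = ""))
#' @export
sketchSequences <- function(seqs, k = 21, s = 1000) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  seqs <- toupper(as.character(seqs))
  if (max(nchar(seqs)) < k)
    stop("empty sketch: every sequence is shorter than k = ", k)
  hashes <- .sketch_cpp(seqs, as.integer(k), as.integer(s), 42)
  if (!length(hashes))
    stop("empty sketch: no valid k-mers (non-ACGT input?)")
  new("Sketch", k = k, s = s, hashes = hashes)
}

#' Mash distance between two sketches
#'
#' The Jaccard index `j` is estimated from the bottom-s sketch of the
#' merged hash sets, then `d = -log(2j / (1 + j)) / k`. Identical sketches
#' give 0; disjoint sketches saturate at 1.
#'
#' @param a,b [Sketch-class] objects with equal `k`.
#' @return Distance in [0, 1].
#' @export
mashDistance <- function(a, b) {
  j <- jaccardEstimate(a, b)
  if (j <= 0) return(1)
  if (j >= 1) return(0)
  -log(2 * j / (1 + j)) / a@k
}

#' @rdname mashDistance
#' @export
jaccardEstimate <- function(a, b) {
  if (a@k != b@k)
    stop("sketches have different k (", a@k, " vs ", b@k, ")")
  s <- min(a@s, b@s)
  merged <- sort(unique(c(a@hashes, b@hashes)))
  bottom <- head(merged, s)
  shared <- sum(bottom %in% a@hashes & bottom %in% b@hashes)
  shared / length(bottom)
}

#' Recommend an aligner and parameters for an assembly pair
#'
#' Same-species pairs use BLAST with word_size 28 and the default
#' WindowMasker `t_thres_pct` 99.5. Cross-species pairs use BLAST with
#' word_size 28 below Mash distance 0.05 and word_size 16 from 0.05 to
#' 0.1 (both with `t_thres_pct` 98.5), and LASTZ with `t_thres_pct` 97.5
#' from 0.1 to 0.3 (with a HoxD55 substitution-matrix note for the most
#' distant pairs, d >= 0.25). Past 0.3 no aligner is recommended:
#' whole-genome alignment is likely uninformative at that distance.
#' Boundaries are left-closed: d = 0.05 gives word_size 16 and d = 0.1
#' gives LASTZ.
#'
#' @param d Mash distance (>= 0).
#' @param sameSpecies are the two assemblies from the same species?
#' @return An [AlignerRecommendation-class].
#' @examples
#' recommendAligner(0.03, sameSpecies = FALSE)
#' @export
recommendAligner <- function(d, sameSpecies = FALSE) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("Mash distance must be a single non-negative number")
  if (sameSpecies) {
    rec <- list("BLAST", 28, 99.5, NA_character_, NA_character_)
  } else if (d < 0.05) {
    rec <- list("BLAST", 28, 98.5, NA_character_, NA_character_)
  } else if (d < 0.1) {
    rec <- list("BLAST", 16, 98.5, NA_character_, NA_character_)
  } else if (d <= 0.3) {
    rec <- list("LASTZ", NA_real_, 97.5,
                if (d >= 0.25) "HoxD55" else NA_character_, NA_character_)
  } else {
    rec <- list("none", NA_real_, NA_real_, NA_character_,
                paste0("Mash distance > 0.3: whole-genome alignment is ",
                       "likely sparse and uninformative at this distance"))
  }
  new("AlignerRecommendation", aligner = rec[[1L]], wordSize = rec[[2L]],
      tThresPct = rec[[3L]], matrixNote = rec[[4L]],
      mashDistance = as.numeric(d), advisory = rec[[5L]])
}

setMethod("show", "AlignerRecommendation", function(object) {
  cat(sprintf("AlignerRecommendation (Mash distance %.4g)\n",
              object@mashDistance))
  if (object@aligner == "BLAST") {
    cat(sprintf("  WindowMasker t_thres_pct: %.1f\n", object@tThresPct))
    cat(sprintf(paste0("  blastn -evalue 0.0001 -gapextend 1 -gapopen 2 ",
                       "-max_target_seqs 250 -soft_masking true ",
                       "-task megablast -window_size 150 -word_size %d\n"),
                as.integer(object@wordSize)))
  } else if (object@aligner == "LASTZ") {
    cat(sprintf("  WindowMasker t_thres_pct: %.1f\n", object@tThresPct))
    cat("  LASTZ via the make_lastz_chains pipeline")
    if (!is.na(object@matrixNote))
      cat(sprintf(" (substitution matrix BLASTZ_Q=%s)", object@matrixNote))
    cat("\n")
  } else {
    cat("  no aligner recommended: ", object@advisory, "\n", sep = "")
  }
})
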