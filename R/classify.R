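CLASS_LEVELS <- c("TYPE_I_FAS", "AFPK", "PKS", "MITO_FASII", "NON_KS")

#' Classifier configuration
#'
#' Bundles the score-space thresholds of the rule classifier: the KS-hit
#' gate (`hit_threshold`, 180 bits by default, the gate used when mining
#' KS domains with full-scale models), and the FAS-score band
#' `[band_low, band_high)` inside which FAS-side sequences are called AFPK.
#' Two taxon presets reflect the published anchor bands: `"mollusc"`
#' (400-600) and `"arthropod"` (200-500).
#'
#' @param hit_threshold Bit-score gate below which nothing is called a KS.
#' @param band_low,band_high AFPK band bounds on the FAS-model bit score.
#' @param preset Optional `"mollusc"` or `"arthropod"`; overrides the band
#'   bounds.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(hit_threshold = 180, band_low = 400,
                              band_high = 600, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("mollusc", "arthropod"))
    if (preset == "mollusc") { band_low <- 400; band_high <- 600 }
    else { band_low <- 200; band_high <- 500 }
  }
  if (!is.numeric(hit_threshold) || hit_threshold <= 0) {
    abort("`hit_threshold` must be positive.")
  }
  if (!is.numeric(band_low) || !is.numeric(band_high) ||
      band_low <= 0 || band_low >= band_high) {
    abort("Band bounds must satisfy 0 < band_low < band_high.")
  }
  structure(list(hit_threshold = hit_threshold, band_low = band_low,
                 band_high = band_high, preset = preset),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config> gate ", x$hit_threshold, " bits; AFPK band [",
      x$band_low, ", ", x$band_high, ")",
      if (!is.null(x$preset)) paste0(" (", x$preset, " preset)"), "\n", sep = "")
  invisible(x)
}

#' Which side of the y = x line?
#'
#' `TRUE` when the PKS-model score strictly exceeds the FAS-model score
#' (PKS side of the diagonal); ties fall on the FAS/AFPK side.
#'
#' @param fas_bits,pks_bits Numeric bit scores (vectorized).
#' @return A logical vector.
#' @examples
#' pks_side(587.7, 274.6)  # FALSE: an AFPK-like score pair
#' pks_side(272.0, 325.6)  # TRUE: a PKS-like score pair
#' @export
pks_side <- function(fas_bits, pks_bits) {
  if (any(!is.finite(fas_bits)) || any(!is.finite(pks_bits))) {
    abort("Scores must be finite.")
  }
  pks_bits > fas_bits
}

#' Score sequences against the three reference models
#'
#' Computes the glocal forward bit score of each sequence against the
#' FAS, PKS and FASII profiles; negative raw scores are clamped to 0
#' ("no alignment").
#'
#' @param seqs A sequence tibble (see [read_fasta()]) or a character vector
#'   of residue strings.
#' @param fas_hmm,pks_hmm,fasii_hmm `profile_hmm` objects.
#' @return A tibble with columns `seq_id`, `fas_bits`, `pks_bits`,
#'   `fasii_bits`.
#' @export
score_triple <- function(seqs, fas_hmm, pks_hmm, fasii_hmm) {
  seqs <- as_sequence_tbl(seqs)
  tibble(
    seq_id = seqs$id,
    fas_bits = pmax(forward_bitscore(fas_hmm, seqs$residues), 0),
    pks_bits = pmax(forward_bitscore(pks_hmm, seqs$residues), 0),
    fasii_bits = pmax(forward_bitscore(fasii_hmm, seqs$residues), 0)
  )
}

as_sequence_tbl <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- tibble(id = sprintf("seq_%03d", seq_along(seqs)), residues = seqs)
  }
  validate_sequences(seqs)
  seqs
}

#' Classify score triples into enzyme classes
#'
#' Applies the score-space decision cascade to each row of a triple table:
#' (1) all three scores below the hit gate: `NON_KS`; (2) the FASII score
#' dominating both type I scores: `MITO_FASII`; (3) PKS side of y = x:
#' `PKS`; (4) FAS score inside `[band_low, band_high)`: `AFPK`; (5) FAS
#' score at or above `band_high`: `TYPE_I_FAS`; (6) otherwise (FAS side but
#' below the band, the continuum tail): `PKS`.
#'
#' @param scores A tibble with columns `fas_bits`, `pks_bits`, `fasii_bits`
#'   (as from [score_triple()]).
#' @param config A [classifier_config()].
#' @return `scores` with an added factor column `label` (levels
#'   `TYPE_I_FAS`, `AFPK`, `PKS`, `MITO_FASII`, `NON_KS`).
#' @examples
#' classify_ks(
#'   tibble::tibble(fas_bits = 587.7, pks_bits = 274.6, fasii_bits = 123.1),
#'   classifier_config(preset = "mollusc")
#' )
#' @export
classify_ks <- function(scores, config = classifier_config()) {
  if (!inherits(config, "classifier_config")) {
    abort("`config` must be a `classifier_config`.")
  }
  need <- c("fas_bits", "pks_bits", "fasii_bits")
  if (!is.data.frame(scores) || !all(need %in% names(scores))) {
    abort("`scores` must contain fas_bits, pks_bits and fasii_bits columns.")
  }
  fas <- scores$fas_bits; pks <- scores$pks_bits; fasii <- scores$fasii_bits
  if (any(!is.finite(c(fas, pks, fasii)))) abort("Scores must be finite.")
  label <- character(nrow(scores))
  top <- pmax(fas, pks, fasii)
  label[top < config$hit_threshold] <- "NON_KS"
  todo <- label == ""
  fasii_dom <- todo & fasii > pmax(fas, pks)
  label[fasii_dom] <- "MITO_FASII"
  todo <- label == ""
  pksy <- todo & pks_side(fas, pks)
  label[pksy] <- "PKS"
  todo <- label == ""
  in_band <- todo & fas >= config$band_low & fas < config$band_high
  label[in_band] <- "AFPK"
  todo <- label == ""
  label[todo & fas >= config$band_high] <- "TYPE_I_FAS"
  label[label == ""] <- "PKS"
  dplyr::mutate(as_tibble(scores), label = factor(label, levels = CLASS_LEVELS))
}

#' Score a sequence panel against a panel of models
#'
#' Glocal forward bit scores of every sequence against every model, clamped
#' at 0, as a wide sequences-by-models table.
#'
#' @param seqs A sequence tibble or character vector of residues.
#' @param hmms A (preferably named) list of `profile_hmm`s.
#' @return A wide tibble: `seq_id` plus one column per model.
#' @export
score_panel <- function(seqs, hmms) {
  seqs <- as_sequence_tbl(seqs)
  if (length(hmms) == 0) abort("`hmms` must be a non-empty list of models.")
  nms <- names(hmms)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(hmms, function(h) h$name, character(1))
  }
  if (anyDuplicated(nms)) abort("Model names must be unique.")
  out <- tibble(seq_id = seqs$id)
  for (j in seq_along(hmms)) {
    out[[nms[j]]] <- pmax(forward_bitscore(hmms[[j]], seqs$residues), 0)
  }
  out
}

#' Dot-plot table of ordered score triples
#'
#' Orders sequences by decreasing FAS-model bit score (ties by `seq_id`),
#' the presentation used to read enzyme-class bands off the score
#' continuum, and attaches the rule-classifier label.
#'
#' @param scores A triple tibble with a `seq_id` column.
#' @param config A [classifier_config()] used for the `label` column.
#' @return A tibble with columns `rank`, `seq_id`, `fas_bits`, `pks_bits`,
#'   `fasii_bits`, `label`.
#' @export
dotplot_table <- function(scores, config = classifier_config()) {
  if (!is.data.frame(scores) || !"seq_id" %in% names(scores)) {
    abort("`scores` must contain a `seq_id` column.")
  }
  out <- classify_ks(scores, config)
  out <- dplyr::arrange(out, dplyr::desc(.data$fas_bits), .data$seq_id)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  dplyr::select(out, "rank", "seq_id", "fas_bits", "pks_bits",
                "fasii_bits", "label")
}

#' Calibrate a classifier configuration on labeled training scores
#'
#' Fits the AFPK band and the hit gate to a labeled training set of score
#' triples. `band_high` is placed midway between the 5th percentile of the
#' FAS scores of `TYPE_I_FAS` training sequences and the 95th percentile of
#' the AFPK ones; `band_low` midway between the 5th percentile of AFPK FAS
#' scores and the 95th percentile of PKS FAS scores. The hit gate is set to
#' half the 1st percentile of the maximum score across the three models
#' among training sequences, so that true KS domains at this model scale
#' pass. Bit scores here are deliberately not comparable to HMMER's, so the
#' published absolute thresholds only apply to full-scale models; this
#' refits them to whatever model scale is in use.
#'
#' @param scores A triple tibble with a `label` column containing at least
#'   `TYPE_I_FAS`, `AFPK` and `PKS`.
#' @return A [classifier_config()].
#' @export
calibrate_config <- function(scores) {
  need <- c("fas_bits", "pks_bits", "fasii_bits", "label")
  if (!is.data.frame(scores) || !all(need %in% names(scores))) {
    abort("`scores` must contain fas/pks/fasii bits and a `label` column.")
  }
  lab <- as.character(scores$label)
  for (cl in c("TYPE_I_FAS", "AFPK", "PKS")) {
    if (!any(lab == cl)) abort(paste0("Training data lacks class ", cl, "."))
  }
  fas <- scores$fas_bits
  q <- function(cl, p) as.numeric(quantile(fas[lab == cl], p, names = FALSE))
  band_high <- (q("TYPE_I_FAS", 0.05) + q("AFPK", 0.95)) / 2
  band_low <- (q("AFPK", 0.05) + q("PKS", 0.95)) / 2
  band_low <- max(band_low, 1e-6)
  if (band_low >= band_high) band_low <- band_high / 2
  top <- pmax(fas, scores$pks_bits, scores$fasii_bits)
  hit <- max(0.5 * as.numeric(quantile(top, 0.01, names = FALSE)), 1e-6)
  classifier_config(hit_threshold = hit, band_low = band_low,
                    band_high = band_high)
}
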