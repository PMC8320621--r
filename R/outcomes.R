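# Margin-exact chemical outcome datasets. The two-scenario predictivity
# evaluation needs per-chemical triples (in vitro call, GHS label, clinical
# signs) whose scenario-wise 2x2 tables equal prescribed counts; any
# per-chemical assignment with the same margins yields identical metrics, so
# the assignment among chemicals is randomized by seed.

TABLE1_GHS_MARGINS <- c(TP = 10, FN = 5, FP = 8, TN = 3)
TABLE1_CLINICAL_MARGINS <- c(TP = 17, FN = 4, FP = 1, TN = 4)

RESPIRATORY_WINDOWS <- c("H0", "H1", "H2")

#' Generate a chemical outcome dataset with prescribed confusion margins
#'
#' Produces \code{n_chemicals} records with a binary in vitro inhibition
#' call, a GHS acute inhalation toxicity category, and raw clinical-sign
#' observations, such that the GHS-scenario and clinical-scenario 2x2 tables
#' against the in vitro call equal the requested margins exactly.
#'
#' @param ghs_margins Named counts \code{c(TP, FN, FP, TN)} for the GHS
#'   scenario (TP: in vitro inhibitory and GHS classified).
#' @param clinical_margins Named counts for the clinical-signs scenario.
#' @param n_chemicals Total number of chemicals; both margin sets must sum to
#'   this, and the in vitro positive totals (TP + FP) must agree across
#'   scenarios (they describe the same in vitro column).
#' @param seed RNG seed controlling which chemicals get which assignment.
#' @return Data frame of chemical records: \code{chemical_id},
#'   \code{invitro_inhibitory} (logical), \code{ghs_category} (one of
#'   \code{"cat3"}, \code{"cat4"}, \code{"not_classified"}),
#'   \code{lc50_mg_per_L} (NA metadata), \code{signs} (raw observations as
#'   \code{"sign@window"} entries separated by \code{";"}; windows H0/H1/H2
#'   are during/up to 2 h post-exposure, \code{"later"} is outside the
#'   scoring window).
#' @export
generate_outcome_dataset <- function(ghs_margins, clinical_margins,
                                     n_chemicals, seed = 1) {
  chk <- function(m, nm) {
    if (!all(c("TP", "FN", "FP", "TN") %in% names(m)) || any(m < 0) ||
        any(m != round(m)))
      stop_cdsurf(paste(nm, "margins need non-negative integer TP/FN/FP/TN"),
                  "consistency_error")
  }
  chk(ghs_margins, "GHS"); chk(clinical_margins, "clinical")
  if (sum(ghs_margins) != n_chemicals || sum(clinical_margins) != n_chemicals)
    stop_cdsurf("margins must sum to n_chemicals in both scenarios",
                "consistency_error")
  n_pos <- ghs_margins[["TP"]] + ghs_margins[["FP"]]
  if (n_pos != clinical_margins[["TP"]] + clinical_margins[["FP"]])
    stop_cdsurf(
      "in vitro positive totals (TP + FP) must agree across scenarios",
      "consistency_error")

  set.seed(seed)
  ids <- sprintf("chem_%02d", seq_len(n_chemicals))
  invitro <- rep(FALSE, n_chemicals)
  invitro[sample.int(n_chemicals, n_pos)] <- TRUE
  pos_idx <- which(invitro); neg_idx <- which(!invitro)

  pick <- function(idx, k) idx[sample.int(length(idx), k)]
  ghs_pos <- logical(n_chemicals)
  ghs_pos[pick(pos_idx, ghs_margins[["TP"]])] <- TRUE
  ghs_pos[pick(neg_idx, ghs_margins[["FN"]])] <- TRUE
  clin_pos <- logical(n_chemicals)
  clin_pos[pick(pos_idx, clinical_margins[["TP"]])] <- TRUE
  clin_pos[pick(neg_idx, clinical_margins[["FN"]])] <- TRUE

  ghs_category <- ifelse(ghs_pos,
                         sample(c("cat3", "cat4"), n_chemicals, replace = TRUE),
                         "not_classified")
  lexicon_terms <- c("irregular respiration", "shallow respiration",
                     "noisy respiration", "slow respiration",
                     "rapid respiration", "gasping")
  signs <- vapply(seq_len(n_chemicals), function(i) {
    if (clin_pos[i]) {
      paste0(sample(lexicon_terms, 1), "@", sample(RESPIRATORY_WINDOWS, 1))
    } else {
      # reference-negative: either no observations, a non-respiratory sign,
      # or a respiratory sign outside the scoring window
      switch(sample.int(3, 1),
             "",
             "piloerection@H0",
             paste0(sample(lexicon_terms, 1), "@later"))
    }
  }, character(1))

  data.frame(chemical_id = ids, invitro_inhibitory = invitro,
             ghs_category = ghs_category, lc50_mg_per_L = NA_real_,
             signs = signs, stringsAsFactors = FALSE)
}

#' Margin-exact 26-chemical benchmark fixture
#'
#' Outcome dataset whose 2x2 margins are the benchmark counts of the
#' two-scenario evaluation: GHS scenario TP=10, FN=5, FP=8, TN=3; clinical
#' scenario TP=17, FN=4, FP=1, TN=4 (26 chemicals, 18 in vitro positives).
#'
#' @param seed RNG seed for the per-chemical assignment (metrics are
#'   seed-invariant; only the assignment order changes).
#' @return Data frame of 26 chemical records (see
#'   \code{\link{generate_outcome_dataset}}).
#' @export
make_table1_fixture <- function(seed = 1) {
  generate_outcome_dataset(TABLE1_GHS_MARGINS, TABLE1_CLINICAL_MARGINS,
                           n_chemicals = 26, seed = seed)
}
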