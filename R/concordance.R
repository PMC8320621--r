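# Two-scenario predictivity evaluation: the binary in vitro inhibition call
# is compared (i) to GHS acute inhalation toxicity classification and (ii) to
# clinical signs of respiratory toxicity observed in rats during exposure and
# up to 2 h post-exposure, via 2x2 tables and the five standard diagnostic
# concordance metrics.

#' Default clinical-sign lexicon and synonym map
#'
#' Six standardized respiratory signs (irregular-, shallow-, noisy-, slow-,
#' rapid/fast-respiration, gasping) plus an editable synonym table mapping
#' raw dossier wording (case-insensitive) onto them. Shipped as YAML under
#' \code{inst/extdata/sign_lexicon.yaml} so the mapping is auditable and
#' editable; unmapped terms are surfaced, never silently dropped.
#'
#' @param path Optional path to an alternative lexicon YAML.
#' @return List with \code{terms} (character vector of lexicon terms) and
#'   \code{synonyms} (named list: raw term -> lexicon term).
#' @export
default_sign_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sign_lexicon.yaml", package = "cdsurf")
  lex <- yaml::read_yaml(path)
  lex$synonyms <- lapply(lex$synonyms, as.character)
  names(lex$synonyms) <- tolower(names(lex$synonyms))
  lex
}

#' Standardize a raw clinical-sign observation
#'
#' Case-insensitive match of the raw wording against the lexicon terms and
#' the synonym table. Unmatched observations return \code{"unmapped"} (a
#' value, not an error), so non-respiratory signs are retained and reportable.
#'
#' @param raw Character vector of raw observations.
#' @param lexicon A lexicon list (see \code{\link{default_sign_lexicon}}).
#' @return Character vector of lexicon terms or \code{"unmapped"}.
#' @export
standardize_clinical_sign <- function(raw, lexicon = default_sign_lexicon()) {
  key <- tolower(trimws(raw))
  vapply(key, function(k) {
    if (k %in% tolower(lexicon$terms))
      return(lexicon$terms[match(k, tolower(lexicon$terms))])
    hit <- lexicon$synonyms[[k]]
    if (!is.null(hit)) hit else "unmapped"
  }, character(1), USE.NAMES = FALSE)
}

# "sign@window;sign@window" -> data frame(raw, window)
parse_signs <- function(signs) {
  if (is.na(signs) || !nzchar(signs))
    return(data.frame(raw = character(0), window = character(0)))
  parts <- strsplit(signs, ";", fixed = TRUE)[[1]]
  mat <- strsplit(trimws(parts), "@", fixed = TRUE)
  bad <- lengths(mat) != 2
  if (any(bad))
    stop_cdsurf(sprintf("malformed sign entry '%s' (expected sign@window)",
                        parts[bad][1]), "schema_error")
  data.frame(raw = vapply(mat, `[`, "", 1),
             window = vapply(mat, `[`, "", 2))
}

#' Clinical reference label of a chemical record
#'
#' TRUE when at least one observation standardizes to a respiratory lexicon
#' term within the scoring windows (H0: during exposure; H1, H2: first and
#' second hour post-exposure). Signs observed later, and unmapped
#' (non-respiratory) signs, do not count.
#'
#' @param signs The record's raw observation string
#'   (\code{"sign@window;..."}, possibly empty).
#' @param lexicon A lexicon list.
#' @return Logical.
#' @export
clinical_reference_label <- function(signs, lexicon = default_sign_lexicon()) {
  obs <- parse_signs(signs)
  if (nrow(obs) == 0) return(FALSE)
  std <- standardize_clinical_sign(obs$raw, lexicon)
  any(std != "unmapped" & obs$window %in% RESPIRATORY_WINDOWS)
}

#' GHS reference label of a chemical record
#'
#' TRUE when the chemical falls under GHS acute inhalation toxicity category
#' 3 or 4 ("classified"); every other value (including "not_classified",
#' category 5 or unclassifiable) is reference-negative.
#'
#' @param ghs_category Character vector of category labels.
#' @return Logical vector.
#' @export
ghs_reference_label <- function(ghs_category) {
  tolower(ghs_category) %in% c("cat3", "cat4")
}

#' Build a 2x2 confusion table for one scenario
#'
#' Crosses the in vitro inhibition call against the scenario's reference
#' label: TP = inhibitory and reference-positive, etc.
#'
#' @param records Chemical record data frame (columns
#'   \code{invitro_inhibitory}, \code{ghs_category}, \code{signs}).
#' @param scenario \code{"ghs"} or \code{"clinical"}.
#' @param lexicon Lexicon for clinical-sign standardization.
#' @return List of class \code{confusion_table}: \code{TP}, \code{FP},
#'   \code{TN}, \code{FN}, \code{n}, \code{scenario}.
#' @export
build_confusion <- function(records, scenario = c("ghs", "clinical"),
                            lexicon = default_sign_lexicon()) {
  scenario <- match.arg(scenario)
  if (nrow(records) == 0)
    stop_cdsurf("no chemical records", "parameter_error")
  pred <- as.logical(records$invitro_inhibitory)
  ref <- if (scenario == "ghs") {
    ghs_reference_label(records$ghs_category)
  } else {
    vapply(records$signs, clinical_reference_label, logical(1),
           lexicon = lexicon, USE.NAMES = FALSE)
  }
  structure(list(TP = sum(pred & ref), FP = sum(pred & !ref),
                 TN = sum(!pred & !ref), FN = sum(!pred & ref),
                 n = nrow(records), scenario = scenario),
            class = "confusion_table")
}

# Wilson score interval for a binomial proportion (no continuity correction)
wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Predictivity metrics from a confusion table
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive value
#' TP/(TP+FP), negative predictive value TN/(TN+FN), accuracy (TP+TN)/N.
#' Exact fractions are retained; display values are rounded half-up to two
#' decimals. A zero denominator yields an undefined (NA) metric with the
#' reason recorded, never a coerced 0/0.
#'
#' @param ct A \code{\link{confusion_table}}.
#' @param conf_level Optional confidence level for Wilson score intervals
#'   (default NULL: no intervals).
#' @return Data frame of class \code{predictivity_metrics}: \code{metric},
#'   \code{numerator}, \code{denominator}, \code{value} (exact),
#'   \code{rounded}, \code{fraction} (display string), optional
#'   \code{ci_lower}/\code{ci_upper}, and \code{note} for undefined metrics.
#' @export
compute_metrics <- function(ct, conf_level = NULL) {
  if (ct$n <= 0) stop_cdsurf("empty confusion table", "parameter_error")
  spec <- list(
    sensitivity = c(ct$TP, ct$TP + ct$FN),
    specificity = c(ct$TN, ct$TN + ct$FP),
    ppv = c(ct$TP, ct$TP + ct$FP),
    npv = c(ct$TN, ct$TN + ct$FN),
    accuracy = c(ct$TP + ct$TN, ct$n))
  out <- do.call(rbind, lapply(names(spec), function(m) {
    num <- spec[[m]][1]; den <- spec[[m]][2]
    val <- if (den > 0) num / den else NA_real_
    data.frame(metric = m, numerator = num, denominator = den,
               value = val, rounded = round_half_up(val, 2),
               fraction = if (den > 0) sprintf("%d/%d", num, den) else NA,
               note = if (den > 0) "" else "undefined: zero denominator")
  }))
  if (!is.null(conf_level)) {
    ci <- t(mapply(function(num, den) {
      if (den > 0) wilson_interval(num, den, conf_level)
      else c(lower = NA_real_, upper = NA_real_)
    }, out$numerator, out$denominator))
    out$ci_lower <- ci[, 1]; out$ci_upper <- ci[, 2]
  }
  class(out) <- c("predictivity_metrics", "data.frame")
  out
}

#' Two-scenario predictivity report
#'
#' Evaluates the in vitro call against both reference scenarios and collects
#' any raw sign wordings that did not map to the lexicon.
#'
#' @param records Chemical record data frame.
#' @param lexicon Lexicon for clinical-sign standardization.
#' @param conf_level Optional confidence level for Wilson intervals.
#' @return List: \code{ghs} and \code{clinical} (each with \code{confusion}
#'   and \code{metrics}) and \code{unmapped_terms}.
#' @export
predictivity_report <- function(records, lexicon = default_sign_lexicon(),
                                conf_level = NULL) {
  all_signs <- do.call(rbind, lapply(records$signs, parse_signs))
  unmapped <- if (nrow(all_signs) > 0) {
    std <- standardize_clinical_sign(all_signs$raw, lexicon)
    sort(unique(all_signs$raw[std == "unmapped"]))
  } else character(0)
  res <- lapply(c(ghs = "ghs", clinical = "clinical"), function(sc) {
    ct <- build_confusion(records, sc, lexicon)
    list(confusion = ct, metrics = compute_metrics(ct, conf_level))
  })
  c(res, list(unmapped_terms = unmapped))
}

#' Format a two-scenario report as a markdown table
#'
#' One row per metric, one column per scenario, each cell showing the
#' rounded value with its exact fraction.
#'
#' @param report Output of \code{\link{predictivity_report}}.
#' @return Character vector of markdown lines.
#' @export
format_report_table <- function(report) {
  g <- report$ghs$metrics; cl <- report$clinical$metrics
  labels <- c(sensitivity = "Sensitivity", specificity = "Specificity",
              ppv = "Positive predictive value",
              npv = "Negative predictive value", accuracy = "Accuracy")
  rows <- vapply(seq_len(nrow(g)), function(i) {
    sprintf("| %s | %.2f (%s) | %.2f (%s) |", labels[g$metric[i]],
            g$rounded[i], g$fraction[i], cl$rounded[i], cl$fraction[i])
  }, character(1))
  c("| Metric | GHS classification | Clinical signs of respiratory toxicity |",
    "|---|---|---|", rows)
}
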