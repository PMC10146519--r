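#' Candidate FID-MS peak matches by Kovats-index tolerance and adjacency
#'
#' A FID peak (with an imputed KI) and an MS peak (with an observed KI) form
#' an accepted candidate pair when they are mutually nearest neighbours, no
#' more than `tol` KI units apart, and each strictly closer to the other than
#' to any alternative peak on either side (a tie with an adjacent alternative
#' rejects the pair: the match must be *clearly* more similar than the peaks
#' immediately before and after). Proximate but rejected pairs are returned
#' with the reason.
#'
#' @param fid_kis,ms_kis sorted, duplicate-free numeric KI vectors.
#' @param tol maximum accepted |KI difference| (default 4).
#' @return data.frame with one row per FID peak's nearest MS peak: `fid_ki`,
#'   `ms_ki`, `delta`, `delta_prev`, `delta_next` (distances from the FID
#'   peak to the MS peaks flanking the matched one), `accepted`, `reason`
#'   (`NA`, `"tolerance"` or `"adjacency"`).
#' @export
candidate_matches <- function(fid_kis, ms_kis, tol = 4) {
  for (v in list(fid_kis, ms_kis))
    if (is.unsorted(v, strictly = TRUE))
      stop("KI lists must be sorted and duplicate-free")
  if (length(fid_kis) == 0 || length(ms_kis) == 0)
    return(data.frame(fid_ki = numeric(), ms_ki = numeric(), delta = numeric(),
                      delta_prev = numeric(), delta_next = numeric(),
                      accepted = logical(), reason = character()))
  rows <- lapply(seq_along(fid_kis), function(i) {
    f <- fid_kis[i]
    d <- abs(f - ms_kis)
    j <- which.min(d)
    delta <- d[j]
    delta_prev <- if (j > 1) d[j - 1] else Inf
    delta_next <- if (j < length(ms_kis)) d[j + 1] else Inf
    # distances from the matched MS peak back to the alternative FID peaks
    dm <- abs(ms_kis[j] - fid_kis)
    rev_ok <- all(delta < dm[-i]) || length(fid_kis) == 1
    fwd_ok <- delta < delta_prev && delta < delta_next
    accepted <- delta <= tol && fwd_ok && rev_ok
    reason <- if (accepted) NA_character_
              else if (!fwd_ok || !rev_ok) "adjacency" else "tolerance"
    data.frame(fid_ki = f, ms_ki = ms_kis[j], delta = delta,
               delta_prev = delta_prev, delta_next = delta_next,
               accepted = accepted, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sex detection and fold-bias code for a peak in one sample type
#'
#' Codes follow the cross-platform comparison convention: a sex is coded
#' `"ALL"` when the peak is detected in every sample of that sex, `"SOME"`
#' when in at least one but not all, `"ND"` when in none, and `"NA"` when
#' that sex was not assayed. A fold-bias flag is set when both sexes have a
#' nonzero mean area and the mean ratio reaches `fold` (default 10).
#'
#' @param male_table,female_table `peak_table`s restricted to one sample
#'   type, or `NULL` for a sex not assayed.
#' @param peak_label the peak.
#' @param fold fold-change needed for the bias flag (compared with `>=`).
#' @return list with `male`, `female` (codes), `bias` (`"male>10x"`,
#'   `"female>10x"` or `"none"`), and `mean_male`, `mean_female`.
#' @export
presence_code <- function(male_table, female_table, peak_label, fold = 10) {
  one <- function(t) {
    if (is.null(t) || nrow(t$areas) == 0)
      return(list(code = "NA", mean = NA_real_))
    j <- match_label(t, peak_label)
    a <- if (is.na(j)) numeric(nrow(t$areas)) else t$areas[, j]
    code <- if (all(a > 0)) "ALL" else if (any(a > 0)) "SOME" else "ND"
    list(code = code, mean = mean(a))
  }
  m <- one(male_table); f <- one(female_table)
  bias <- "none"
  if (!is.na(m$mean) && !is.na(f$mean) && m$mean > 0 && f$mean > 0) {
    if (m$mean / f$mean >= fold) bias <- "male>10x"
    else if (f$mean / m$mean >= fold) bias <- "female>10x"
  }
  list(male = m$code, female = f$code, bias = bias,
       mean_male = m$mean, mean_female = f$mean)
}

#' Bundle per-sample-type presence codes for one peak
#'
#' @param codes named list with elements `virgin` and/or `mixed`, each a
#'   [presence_code()] result; a missing sample type counts as not assayed.
#' @return list of class `presence_codes`.
#' @export
presence_codes <- function(codes) {
  structure(list(virgin = codes$virgin %||% NULL,
                 mixed = codes$mixed %||% NULL),
            class = "presence_codes")
}

#' Rate the sex/mating-category compatibility of a matched peak pair
#'
#' Detection states from the two platforms are compared per sample type and
#' sex, with `"ALL"` and `"SOME"` collapsed to "present" and `"NA"`
#' compatible with anything. A pair with no presence/absence disagreement is
#' rated `"YY"` (high). A disagreement is forgiven - rating `"Y"`
#' (acceptable) - when the presence side is `"SOME"` and the peak's maximum
#' abundance class is only minor, or when the presence side still shows a
#' greater-than-`fold` mean bias toward the sex in question. Any other
#' disagreement rates the pair `"N"` (incompatible). Note the bias clause is
#' strict (`>`), whereas the flag inside [presence_code()] uses `>=`; each
#' follows its own defining rule.
#'
#' @param fid_code,ms_code `presence_codes` (or plain lists with `virgin` /
#'   `mixed` entries) for the FID and MS sides.
#' @param fid_abundance_class `"major"`, `"intermediate"` or `"minor"`.
#' @param fold fold threshold for the bias forgiveness clause (strict `>`).
#' @return `"YY"`, `"Y"` or `"N"`.
#' @export
compatibility_rating <- function(fid_code, ms_code, fid_abundance_class,
                                 fold = 10) {
  state <- function(code) {
    if (is.null(code) || code == "NA") "na"
    else if (code %in% c("ALL", "SOME")) "present"
    else "nd"
  }
  disagreements <- list()
  for (st in c("virgin", "mixed")) {
    fc <- fid_code[[st]]; mc <- ms_code[[st]]
    for (sex in c("male", "female")) {
      sf <- state(if (is.null(fc)) NULL else fc[[sex]])
      sm <- state(if (is.null(mc)) NULL else mc[[sex]])
      if (sf == "na" || sm == "na" || sf == sm) next
      pres <- if (sf == "present") fc else mc
      pres_code <- pres[[sex]]
      biased <- bias_toward(pres, sex, fold)
      disagreements[[length(disagreements) + 1]] <-
        list(presence_is_some = pres_code == "SOME", biased = biased)
    }
  }
  if (length(disagreements) == 0) return("YY")
  forgivable <- vapply(disagreements, function(d) {
    (d$presence_is_some && fid_abundance_class == "minor") || d$biased
  }, logical(1))
  if (all(forgivable)) "Y" else "N"
}

# fold bias is defined only when both sexes have a nonzero mean: a
# sex-specific presence is a presence/absence pattern, not a fold bias
bias_toward <- function(code, sex, fold) {
  mm <- code$mean_male; mf <- code$mean_female
  if (is.na(mm) || is.na(mf) || mm <= 0 || mf <= 0) return(FALSE)
  if (sex == "male") mm / mf > fold else mf / mm > fold
}

#' Resolve rated candidates into the final cross-platform match set
#'
#' Accepted pairs are the tolerance+adjacency candidates minus peaks whose
#' identity was already established against authentic standards (reported
#' separately) and minus pairs rated incompatible (`"N"`). The result is a
#' partial one-to-one pairing; a conflicting assignment (which the
#' mutual-nearest rule should preclude) is an error.
#'
#' @param candidates output of [candidate_matches()], with an added `rating`
#'   column (`"YY"`, `"Y"`, `"N"` or `NA` for unrated).
#' @param already_identified numeric vector of FID KI labels whose identity
#'   is already known.
#' @return list with `accepted`, `already_identified`, `rejected` (with a
#'   `reason` column), `unmatched_fid`, `unmatched_ms` (KI vectors).
#' @export
assign_spectra <- function(candidates, already_identified = numeric()) {
  if (is.null(candidates$rating))
    candidates$rating <- rep(NA_character_, nrow(candidates))
  cand <- candidates[candidates$accepted, , drop = FALSE]
  rej <- candidates[!candidates$accepted, , drop = FALSE]
  known <- cand$fid_ki %in% already_identified
  known_rows <- cand[known, , drop = FALSE]
  cand <- cand[!known, , drop = FALSE]
  bad <- !is.na(cand$rating) & cand$rating == "N"
  if (any(bad)) {
    nrow_rej <- cand[bad, , drop = FALSE]
    nrow_rej$reason <- "incompatible"
    rej <- rbind(rej, nrow_rej)
    cand <- cand[!bad, , drop = FALSE]
  }
  if (nrow(known_rows)) known_rows$reason <- "already_identified"
  if (anyDuplicated(cand$fid_ki) || anyDuplicated(cand$ms_ki))
    stop("conflicting assignments: a peak appears in more than one accepted pair")
  list(accepted = cand,
       already_identified = known_rows,
       rejected = rej,
       unmatched_fid = setdiff(candidates$fid_ki,
                               c(cand$fid_ki, known_rows$fid_ki)),
       unmatched_ms = setdiff(candidates$ms_ki,
                              c(cand$ms_ki, known_rows$ms_ki)))
}
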