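# Choline-challenge metabolics: pick the post-challenge urine collection with
# the highest TMA, compute the TMAO fraction of total TMA species, and apply
# the 0.90 reference to call TMAU.

#' Read a urine-collection table
#'
#' Tab-delimited with header columns `subject_id`, `interval_index`
#' (0 = first-morning pre-challenge, 1-3 = consecutive 8-hour post-challenge
#' collections), optional `volume_ml`, `tma_conc` and optional `tmao_conc`
#' (measured only on the selected collection); `"."` marks missing values.
#'
#' @param path Path to the TSV file.
#' @return A data frame, one row per (subject, interval).
#' @export
read_urine_table <- function(path) {
  u <- utils::read.delim(path, sep = "\t", header = TRUE,
                         na.strings = c(".", ""), stringsAsFactors = FALSE)
  req <- c("subject_id", "interval_index", "tma_conc")
  miss <- setdiff(req, names(u))
  if (length(miss))
    stop("urine table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"volume_ml" %in% names(u)) u$volume_ml <- NA_real_
  if (!"tmao_conc" %in% names(u)) u$tmao_conc <- NA_real_
  u$subject_id <- as.character(u$subject_id)
  u$interval_index <- as.integer(u$interval_index)
  for (col in c("volume_ml", "tma_conc", "tmao_conc"))
    u[[col]] <- as.numeric(u[[col]])
  if (anyDuplicated(u[c("subject_id", "interval_index")]))
    stop("interval_index must be unique per subject")
  neg <- function(x) any(!is.na(x) & x < 0)
  if (neg(u$tma_conc) || neg(u$tmao_conc))
    stop("concentrations must be non-negative")
  u
}

#' Select the peak post-challenge urine sample
#'
#' Returns the interval index of the post-challenge collection with the
#' highest TMA concentration; this is the sample on which TMAO is measured.
#' Ties are broken by the earliest interval. The pre-challenge collection
#' (interval 0) is excluded unless `include_pre = TRUE`.
#'
#' @param samples Data frame of urine rows for one subject (columns
#'   `interval_index`, `tma_conc`).
#' @param include_pre Consider the interval-0 collection as well?
#' @return The selected `interval_index` (integer scalar).
#' @export
select_peak_sample <- function(samples, include_pre = FALSE) {
  if (!is.data.frame(samples) || !nrow(samples))
    stop("no urine samples supplied")
  s <- samples[!is.na(samples$tma_conc), , drop = FALSE]
  if (!include_pre) s <- s[s$interval_index > 0L, , drop = FALSE]
  if (!nrow(s))
    stop("no post-challenge sample with a TMA measurement")
  s <- s[order(-s$tma_conc, s$interval_index), , drop = FALSE]
  as.integer(s$interval_index[1L])
}

#' TMA oxidation ratio
#'
#' The TMAO fraction of total TMA species, `tmao / (tma + tmao)`, which lies
#' in `[0, 1]`; a value of 1 means fully oxidized. The raw quotient
#' `tmao / tma` is exposed separately by [metabolic_profiles()].
#'
#' @param tma_conc,tmao_conc Non-negative concentrations in consistent units
#'   (the ratio is scale-invariant). Vectorized; a pair may not be both zero.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @examples
#' oxidation_ratio(87, 13)  # 0.13
#' @export
oxidation_ratio <- function(tma_conc, tmao_conc) {
  if (any(is.na(tma_conc)) || any(is.na(tmao_conc)))
    stop("concentrations must not be missing")
  if (any(tma_conc < 0) || any(tmao_conc < 0))
    stop("concentrations must be non-negative")
  tot <- tma_conc + tmao_conc
  if (any(tot == 0))
    stop("oxidation ratio undefined when both TMA and TMAO are zero")
  tmao_conc / tot
}

#' Classify TMAU status from an oxidation ratio
#'
#' A subject is called TMAU when the ratio falls strictly below the reference
#' threshold (default 0.90); a ratio exactly at the threshold is NORMAL. Set
#' `strict = FALSE` to also call the boundary value TMAU.
#'
#' @param ratio Oxidation ratio(s) in `[0, 1]`.
#' @param threshold Reference threshold (default 0.90).
#' @param strict Use strict inequality (default `TRUE`).
#' @return Character vector, `"TMAU"` or `"NORMAL"`.
#' @export
classify_tmau <- function(ratio, threshold = 0.90, strict = TRUE) {
  if (any(is.na(ratio)) || any(ratio < 0) || any(ratio > 1))
    stop("ratio must lie in [0, 1]")
  low <- if (strict) ratio < threshold else ratio <= threshold
  ifelse(low, "TMAU", "NORMAL")
}

#' Per-subject metabolic profiles
#'
#' For each subject: select the peak post-challenge sample, compute the
#' oxidation ratio from that sample's TMA and TMAO, and classify TMAU status.
#'
#' @param urine Urine table as returned by [read_urine_table()].
#' @param threshold,strict Passed to [classify_tmau()].
#' @param include_pre Passed to [select_peak_sample()].
#' @return A `metabolic_profiles` data frame with columns `subject_id`,
#'   `selected_interval`, `tma_conc`, `tmao_conc`, `ratio`, `raw_quotient`
#'   (`tmao/tma`, `Inf` when TMA is zero) and `status`, sorted by ascending
#'   ratio.
#' @export
metabolic_profiles <- function(urine, threshold = 0.90, strict = TRUE,
                               include_pre = FALSE) {
  ids <- unique(urine$subject_id)
  rows <- lapply(ids, function(id) {
    s <- urine[urine$subject_id == id, , drop = FALSE]
    sel <- select_peak_sample(s, include_pre = include_pre)
    r <- s[s$interval_index == sel, , drop = FALSE]
    if (is.na(r$tmao_conc))
      stop("subject ", id, ": no TMAO measurement on the selected sample ",
           "(interval ", sel, ")")
    ratio <- oxidation_ratio(r$tma_conc, r$tmao_conc)
    data.frame(
      subject_id = id, selected_interval = sel,
      tma_conc = r$tma_conc, tmao_conc = r$tmao_conc, ratio = ratio,
      raw_quotient = if (r$tma_conc > 0) r$tmao_conc / r$tma_conc else Inf,
      status = classify_tmau(ratio, threshold, strict),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ratio, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("metabolic_profiles", "data.frame")
  out
}

#' Summarize a cohort of metabolic profiles
#'
#' @param profiles A [metabolic_profiles()] data frame.
#' @return A list with `n`, `n_tmau`, `min_ratio`, `max_ratio`.
#' @export
summarize_cohort <- function(profiles) {
  if (!is.data.frame(profiles) || !nrow(profiles))
    stop("no metabolic profiles supplied")
  list(
    n = nrow(profiles),
    n_tmau = sum(profiles$status == "TMAU"),
    min_ratio = min(profiles$ratio),
    max_ratio = max(profiles$ratio)
  )
}
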