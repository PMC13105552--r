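#' Published aggregate screening-cascade counts of the programme
#'
#' Invitees, initial-screen completers, screen positives, colonoscopies,
#' detections by lesion class, total screening cost (USD) and modelled CRC
#' deaths averted, as published for the province-wide programme (2020-2024).
#'
#' @return One-row tibble.
#' @export
pccsp_counts <- function() {
  readr::read_csv(
    system.file("extdata", "pccsp_counts.csv", package = "crcscreen",
                mustWork = TRUE),
    col_types = readr::cols(stratum = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
}

#' Published cascade and yield metrics, as printed
#'
#' The rates and per-lesion resource metrics the programme reported. Used by
#' [yield_report()] to surface arithmetic discrepancies between printed
#' cells and the printed input counts.
#'
#' @return Tibble `metric`, `lesion`, `value`.
#' @export
pccsp_reference_metrics <- function() {
  tibble::tribble(
    ~metric, ~lesion, ~value,
    "participation_pct", "all", 58.29,
    "positivity_pct", "all", 15.27,
    "compliance_pct", "all", 38.92,
    "detection_rate_pct", "naa", 21.18,
    "detection_rate_pct", "aa", 11.55,
    "detection_rate_pct", "crc", 1.10,
    "yield_per_10k_participants", "naa", 43,
    "yield_per_10k_participants", "aa", 24,
    "yield_per_10k_participants", "crc", 3,
    "yield_per_10k_participants", "an", 26,
    "yield_per_10k_colonoscopies", "naa", 825,
    "yield_per_10k_colonoscopies", "aa", 450,
    "yield_per_10k_colonoscopies", "crc", 43,
    "yield_per_10k_colonoscopies", "an", 493,
    "colonoscopies_per_lesion", "naa", 6,
    "colonoscopies_per_lesion", "aa", 11,
    "colonoscopies_per_lesion", "crc", 108,
    "colonoscopies_per_lesion", "an", 10,
    "cost_per_lesion", "naa", 835,
    "cost_per_lesion", "aa", 1588,
    "cost_per_lesion", "crc", 16684,
    "cost_per_lesion", "an", 1450,
    "nns_initial", "crc", 532,
    "nns_clinical", "crc", 64
  )
}

#' Screening-cascade rates
#'
#' Participation (completers/invitees), positivity (positives/completers),
#' colonoscopy compliance (colonoscopies/positives) and per-lesion detection
#' rates (detections/colonoscopies), reported as percentages to two
#' decimals.
#'
#' @param counts One-row tibble shaped like [pccsp_counts()].
#' @return One-row tibble of percentages.
#' @export
#' @examples
#' cascade_rates(pccsp_counts())
cascade_rates <- function(counts) {
  stopifnot(nrow(counts) == 1)
  pct <- function(num, den) {
    if (den == 0) stop("zero denominator in cascade rate", call. = FALSE)
    round_half_up(100 * num / den, 2)
  }
  with(counts, {
    if (completers > invitees || positives > completers ||
        colonoscopies > positives) {
      stop("cascade counts violate ordering invariants", call. = FALSE)
    }
    tibble::tibble(
      participation_pct = pct(completers, invitees),
      positivity_pct = pct(positives, completers),
      compliance_pct = pct(colonoscopies, positives),
      detection_rate_naa_pct = pct(detected_naa, colonoscopies),
      detection_rate_aa_pct = pct(detected_aa, colonoscopies),
      detection_rate_crc_pct = pct(detected_crc, colonoscopies),
      detection_rate_an_pct = pct(detected_aa + detected_crc, colonoscopies)
    )
  })
}

#' Yield per 10,000 initial-screening participants
#'
#' `10,000 x participation x positivity x colonoscopy compliance x detection
#' rate`, rounded half-up to an integer.
#'
#' @param participation,positivity,compliance,detection_rate Probabilities.
#' @return Integer count per 10,000 participants.
#' @export
yield_per_10k_participants <- function(participation, positivity,
                                       compliance, detection_rate) {
  stopifnot(all(c(participation, positivity, compliance,
                  detection_rate) >= 0),
            all(c(participation, positivity, compliance,
                  detection_rate) <= 1))
  round_half_up(1e4 * participation * positivity * compliance *
                  detection_rate)
}

#' Yield per 10,000 colonoscopies
#'
#' `10,000 x colonoscopy compliance x detection rate`, rounded half-up.
#'
#' @param compliance,detection_rate Probabilities.
#' @return Integer count per 10,000 colonoscopies.
#' @export
#' @examples
#' yield_per_10k_colonoscopies(0.3892, 0.0110)
yield_per_10k_colonoscopies <- function(compliance, detection_rate) {
  stopifnot(compliance >= 0, compliance <= 1,
            detection_rate >= 0, detection_rate <= 1)
  round_half_up(1e4 * compliance * detection_rate)
}

#' Colonoscopies needed to detect one lesion
#'
#' Ceiling quotient: the smallest whole number of colonoscopies per
#' detection.
#'
#' @param colonoscopies,detections Counts.
#' @return Integer; errors when `detections` is zero.
#' @export
colonoscopies_per_lesion <- function(colonoscopies, detections) {
  if (any(detections == 0)) {
    stop("colonoscopies per lesion undefined with zero detections",
         call. = FALSE)
  }
  ceiling(colonoscopies / detections)
}

#' Cost to detect one lesion
#'
#' @param total_cost Total screening cost in USD.
#' @param detections Lesions detected.
#' @return USD per lesion, rounded half-up to the nearest dollar.
#' @export
cost_per_lesion <- function(total_cost, detections) {
  if (any(detections <= 0)) {
    stop("cost per lesion requires a positive detection count",
         call. = FALSE)
  }
  round_half_up(total_cost / detections)
}

#' Number needed to screen per CRC death averted
#'
#' Initial NNS = initial-screen completers per death averted; clinical NNS =
#' colonoscopies per death averted. Both rounded half-up.
#'
#' @param screeners Initial-screen completers.
#' @param colonoscopies Colonoscopies performed.
#' @param deaths_averted CRC deaths averted; must be positive.
#' @return One-row tibble `nns_initial`, `nns_clinical`.
#' @export
nns_per_death_averted <- function(screeners, colonoscopies, deaths_averted) {
  if (any(deaths_averted <= 0)) {
    stop("NNS undefined with no deaths averted", call. = FALSE)
  }
  tibble::tibble(
    nns_initial = round_half_up(screeners / deaths_averted),
    nns_clinical = round_half_up(colonoscopies / deaths_averted)
  )
}

#' Full programme-yield report with discrepancy listing
#'
#' Recomputes every cascade rate, yield and resource metric from aggregate
#' counts via the stated formulas and, when reference (printed) metrics are
#' supplied, lists every cell whose printed value is not arithmetically
#' consistent with the printed counts. Discrepant cells are reported, never
#' silently matched. Advanced-neoplasm (AN) metrics use the AA + CRC counts.
#'
#' @param counts One-row tibble shaped like [pccsp_counts()].
#' @param reference Optional tibble like [pccsp_reference_metrics()].
#' @return A `crc_yield` list: `rates` (cascade percentages), `report`
#'   (metric x lesion tibble) and `discrepancies` (computed vs printed with
#'   a `consistent` flag), or `NULL` when no reference is given.
#' @export
#' @examples
#' rep <- yield_report(pccsp_counts(), pccsp_reference_metrics())
#' rep$discrepancies
yield_report <- function(counts, reference = NULL) {
  rates <- cascade_rates(counts)
  det <- c(naa = counts$detected_naa, aa = counts$detected_aa,
           crc = counts$detected_crc,
           an = counts$detected_aa + counts$detected_crc)
  p_part <- counts$completers / counts$invitees
  p_pos <- counts$positives / counts$completers
  p_comp <- counts$colonoscopies / counts$positives
  det_rate <- det / counts$colonoscopies

  report <- tibble::tibble(
    lesion = names(det),
    detections = unname(det),
    detection_rate_pct = round_half_up(100 * det_rate, 2),
    yield_per_10k_participants = yield_per_10k_participants(
      p_part, p_pos, p_comp, det_rate),
    yield_per_10k_colonoscopies = yield_per_10k_colonoscopies(
      p_comp, det_rate),
    colonoscopies_per_lesion = colonoscopies_per_lesion(
      counts$colonoscopies, det),
    invitees_per_lesion = round_half_up(counts$invitees / det),
    cost_per_lesion = cost_per_lesion(counts$total_cost_usd, det)
  )
  nns <- if (!is.na(counts$crc_deaths_averted) &&
             counts$crc_deaths_averted > 0) {
    nns_per_death_averted(counts$completers, counts$colonoscopies,
                          counts$crc_deaths_averted)
  } else {
    tibble::tibble(nns_initial = NA_real_, nns_clinical = NA_real_)
  }

  discrepancies <- NULL
  if (!is.null(reference)) {
    computed <- dplyr::bind_rows(
      tibble::tibble(metric = "participation_pct", lesion = "all",
                     computed = rates$participation_pct),
      tibble::tibble(metric = "positivity_pct", lesion = "all",
                     computed = rates$positivity_pct),
      tibble::tibble(metric = "compliance_pct", lesion = "all",
                     computed = rates$compliance_pct),
      report |>
        tidyr::pivot_longer(-c("lesion", "detections"),
                            names_to = "metric", values_to = "computed"),
      tibble::tibble(metric = c("nns_initial", "nns_clinical"),
                     lesion = "crc",
                     computed = c(nns$nns_initial, nns$nns_clinical))
    )
    discrepancies <- reference |>
      dplyr::rename(printed = "value") |>
      dplyr::inner_join(computed, by = c("metric", "lesion")) |>
      dplyr::mutate(consistent = .data$computed == .data$printed)
  }

  structure(
    list(rates = rates, report = report, nns = nns,
         discrepancies = discrepancies),
    class = "crc_yield"
  )
}

#' @export
print.crc_yield <- function(x, ...) {
  cat("<crc_yield>\n")
  print(x$rates)
  print(x$report)
  if (!is.null(x$discrepancies)) {
    n_bad <- sum(!x$discrepancies$consistent)
    cat(n_bad, "printed cell(s) not reproducible from the printed counts\n")
  }
  invisible(x)
}
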