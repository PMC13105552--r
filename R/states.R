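#' The 21-state health-state space
#'
#' The model follows the adenoma-carcinoma sequence: normal epithelium may
#' develop a non-advanced adenoma (NAA), progress to an advanced adenoma (AA)
#' and on to preclinical colorectal cancer (CRC) stages I-IV. Each lesion/CRC
#' class exists in three compartments: undiagnosed (`_u`), diagnosed and
#' treated (`_t`, under surveillance or post-treatment follow-up) and
#' diagnosed but untreated (`_du`, treatment declined). Two absorbing death
#' states close the space. Progression is irreversible within the undiagnosed
#' and diagnosed-untreated compartments; recurrence returns a treated state to
#' the corresponding undiagnosed state, where the lesion must be re-detected.
#'
#' @return A tibble with one row per state: `state`, `class` (normal, naa,
#'   aa, crc1-crc4, death), `compartment` (undiagnosed, treated,
#'   diagnosed_untreated, death) and the column index used throughout the
#'   engine.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  tibble::tibble(
    state = c(
      "normal",
      "naa_u", "aa_u", "crc1_u", "crc2_u", "crc3_u", "crc4_u",
      "naa_t", "aa_t", "crc1_t", "crc2_t", "crc3_t", "crc4_t",
      "naa_du", "aa_du", "crc1_du", "crc2_du", "crc3_du", "crc4_du",
      "death_crc", "death_other"
    ),
    class = c(
      "normal",
      "naa", "aa", "crc1", "crc2", "crc3", "crc4",
      "naa", "aa", "crc1", "crc2", "crc3", "crc4",
      "naa", "aa", "crc1", "crc2", "crc3", "crc4",
      "death", "death"
    ),
    compartment = c(
      "undiagnosed",
      rep("undiagnosed", 6),
      rep("treated", 6),
      rep("diagnosed_untreated", 6),
      "death", "death"
    ),
    index = seq_len(21L)
  )
}

# engine-internal index constants
.S <- list(
  normal = 1L,
  naa_u = 2L, aa_u = 3L, crc1_u = 4L, crc2_u = 5L, crc3_u = 6L, crc4_u = 7L,
  naa_t = 8L, aa_t = 9L, crc1_t = 10L, crc2_t = 11L, crc3_t = 12L,
  crc4_t = 13L,
  naa_du = 14L, aa_du = 15L, crc1_du = 16L, crc2_du = 17L, crc3_du = 18L,
  crc4_du = 19L,
  death_crc = 20L, death_other = 21L
)

.state_names <- c(
  "normal",
  "naa_u", "aa_u", "crc1_u", "crc2_u", "crc3_u", "crc4_u",
  "naa_t", "aa_t", "crc1_t", "crc2_t", "crc3_t", "crc4_t",
  "naa_du", "aa_du", "crc1_du", "crc2_du", "crc3_du", "crc4_du",
  "death_crc", "death_other"
)

#' Default initial cohort distribution
#'
#' A closed cohort enters the model lesion-free: all probability mass in the
#' `normal` state. Supply a different named vector to [run_cohort()] to start
#' from an age-specific initial health-state mix instead.
#'
#' @return Named numeric vector of length 21 summing to 1.
#' @export
initial_distribution <- function() {
  m <- stats::setNames(numeric(21L), .state_names)
  m["normal"] <- 1
  m
}
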