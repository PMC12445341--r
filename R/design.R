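#' Default synthetic drought-intensity levels
#'
#' Nine soil-water-deficit (SWD, percent of field capacity) levels spread over
#' 40--98%, four at or below 75% and five at or above 80%, so that
#' discretising a gradient at the 76% cutoff yields legacy groups of size
#' 5 (control) / 4 (mild) / 5 (severe) per gradient.
#'
#' @return Numeric vector of 9 SWD percentages.
#' @export
default_drought_levels <- function() c(40, 52, 64, 75, 80, 84.5, 89, 93.5, 98)

#' Build a drought-gradient mesocosm design
#'
#' Generates the experimental design of a two-year soil drought-legacy study:
#' in year 1, each plant community (resource-acquisition strategy) is grown on
#' replicated gradients of increasing soil water deficit (SWD); in year 2, the
#' gradients are split over a drought/control treatment crossed with two
#' destructive-harvest timepoints (peak drought and recovery). Each gradient
#' holds `control_reps` well-watered controls plus one mesocosm per drought
#' level, and whole gradients are assigned round-robin to the four
#' (year-2 treatment x timepoint) combinations.
#'
#' With the defaults (2 strategies, 4 gradients each, 5 control replicates,
#' 9 drought levels) the design has `2 * 4 * (5 + 9) = 112` units, 14 per
#' gradient.
#'
#' @param n_strategies number of plant community strategies (1 = fast only,
#'   2 = fast and slow).
#' @param n_gradients_per_strategy number of replicate gradients per strategy.
#' @param control_swd SWD (%) of the well-watered control, default 20.
#' @param control_reps number of control replicates per gradient (must be
#'   at least 1).
#' @param drought_levels distinct SWD percentages, all above `control_swd`.
#' @return A `data.frame` with one row per experimental unit and columns
#'   `unit_id`, `gradient_id`, `plant_strategy`, `swd_2020`, `replicate`,
#'   `year2_treatment`, `timepoint`.
#' @examples
#' d <- build_design()
#' nrow(d)              # 112
#' table(d$gradient_id) # 14 per gradient
#' @export
build_design <- function(n_strategies = 2,
                         n_gradients_per_strategy = 4,
                         control_swd = 20,
                         control_reps = 5,
                         drought_levels = default_drought_levels()) {
  if (n_strategies < 0 || n_strategies > 2)
    stop("`n_strategies` must be 1 (fast) or 2 (fast + slow)")
  if (control_reps < 1) stop("`control_reps` must be at least 1")
  if (anyDuplicated(drought_levels)) stop("duplicate drought levels")
  if (length(drought_levels) && any(drought_levels <= control_swd))
    stop("all drought levels must exceed `control_swd`")

  strategies <- c("fast", "slow")[seq_len(n_strategies)]
  combos <- expand.grid(year2_treatment = c("drought", "control"),
                        timepoint = c("peak", "recovery"),
                        stringsAsFactors = FALSE)

  rows <- list()
  gid <- 0L
  for (strat in strategies) {
    for (g in seq_len(n_gradients_per_strategy)) {
      gid <- gid + 1L
      cmb <- combos[((g - 1L) %% nrow(combos)) + 1L, ]
      swd <- c(rep(control_swd, control_reps), drought_levels)
      rep_no <- c(seq_len(control_reps), rep(1L, length(drought_levels)))
      rows[[gid]] <- data.frame(
        unit_id = sprintf("%s_g%02d_swd%04.1f_r%d", strat, gid, swd, rep_no),
        gradient_id = gid,
        plant_strategy = strat,
        swd_2020 = swd,
        replicate = rep_no,
        year2_treatment = cmb$year2_treatment,
        timepoint = cmb$timepoint,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(unit_id = character(), gradient_id = integer(),
                      plant_strategy = character(), swd_2020 = numeric(),
                      replicate = integer(), year2_treatment = character(),
                      timepoint = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
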