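#' Synthetic taxonomy for a two-kingdom ASV pool
#'
#' Generates taxon identifiers with kingdom, phylum and family labels for a
#' pool of prokaryote-like and fungal-like ASVs. Families nest in phyla;
#' family sizes are uneven (geometric-ish), as in real amplicon data, and a
#' small fraction of taxa is left with an unknown family.
#'
#' @param n_prokaryote,n_fungal number of taxa per kingdom (defaults 150/80).
#' @param taxa_per_family,families_per_phylum average nesting sizes.
#' @param prop_unknown_family fraction of taxa with family `"unknown"`.
#' @param seed integer seed.
#' @return `data.frame` with columns `taxon_id`, `kingdom`, `phylum`, `family`.
#' @export
synth_taxonomy <- function(n_prokaryote = 150, n_fungal = 80,
                           taxa_per_family = 8, families_per_phylum = 5,
                           prop_unknown_family = 0.05, seed = 1) {
  one_kingdom <- function(n, kingdom, prefix) {
    if (n == 0) return(NULL)
    n_fam <- max(1L, ceiling(n / taxa_per_family))
    fam_of <- sort(rep_len(seq_len(n_fam), n))
    phy_of_fam <- ceiling(seq_len(n_fam) / families_per_phylum)
    df <- data.frame(
      taxon_id = sprintf("%s%04d", prefix, seq_len(n)),
      kingdom = kingdom,
      phylum = sprintf("%s_phylum_%02d", kingdom, phy_of_fam[fam_of]),
      family = sprintf("%s_family_%03d", kingdom, fam_of),
      stringsAsFactors = FALSE
    )
    df
  }
  tax <- rbind(one_kingdom(n_prokaryote, "prokaryote", "pASV"),
               one_kingdom(n_fungal, "fungal", "fASV"))
  with_seed(child_seed(seed, 21L), {
    n_unk <- round(prop_unknown_family * nrow(tax))
    if (n_unk > 0) tax$family[sample.int(nrow(tax), n_unk)] <- "unknown"
  })
  rownames(tax) <- NULL
  tax
}

#' Specify per-taxon drought-legacy effects on latent abundance
#'
#' Builds the legacy-effect specification the count simulator consumes: a
#' per-taxon slope of latent log-abundance versus past soil water deficit
#' (SWD 2020, per 100% SWD), a per-taxon shift applied under the year-2
#' drought treatment, and a baseline log-abundance giving the pool its
#' uneven rank-abundance profile. Responses are scaled per kingdom with the
#' prokaryote-like scale at least the fungal-like scale, encoding the
#' assumption that past drought restructures prokaryote communities more
#' strongly than fungal ones.
#'
#' @param taxonomy taxonomy `data.frame` as from [synth_taxonomy()] (needs
#'   `taxon_id` and `kingdom` columns).
#' @param prop_responsive fraction of taxa with a non-zero legacy slope.
#' @param slope_range magnitude range (per 100% SWD, latent log units) from
#'   which responsive slopes are drawn, with random sign.
#' @param effect_scale named multipliers per kingdom; the prokaryote-like
#'   scale must be >= the fungal-like scale >= 0.
#' @param year2_drought_sd sd of the per-taxon latent shift applied to units
#'   under the year-2 drought treatment (0 disables the year-2 effect).
#' @param base_abundance_sd sd of per-taxon baseline log-abundances.
#' @param seed integer seed.
#' @return `data.frame` of class `legacy_effects` with columns `taxon_id`,
#'   `kingdom`, `slope`, `year2_shift`, `base`.
#' @export
legacy_effects <- function(taxonomy,
                           prop_responsive = 0.3,
                           slope_range = c(0.5, 2),
                           effect_scale = c(prokaryote = 1, fungal = 0.4),
                           year2_drought_sd = 0.5,
                           base_abundance_sd = 1.5,
                           seed = 1) {
  stopifnot(all(c("taxon_id", "kingdom") %in% names(taxonomy)))
  if (!all(c("prokaryote", "fungal") %in% names(effect_scale)))
    effect_scale <- c(prokaryote = unname(effect_scale[1]),
                      fungal = unname(effect_scale[min(2, length(effect_scale))]))
  if (effect_scale[["prokaryote"]] < effect_scale[["fungal"]] ||
      effect_scale[["fungal"]] < 0)
    stop("effect scales must satisfy prokaryote >= fungal >= 0")
  n <- nrow(taxonomy)
  scale_of <- ifelse(taxonomy$kingdom == "prokaryote",
                     effect_scale[["prokaryote"]], effect_scale[["fungal"]])
  out <- with_seed(child_seed(seed, 22L), {
    responsive <- runif(n) < prop_responsive
    slope <- numeric(n)
    k <- sum(responsive)
    if (k > 0)
      slope[responsive] <- sample(c(-1, 1), k, TRUE) *
        runif(k, slope_range[1], slope_range[2])
    data.frame(
      taxon_id = taxonomy$taxon_id,
      kingdom = taxonomy$kingdom,
      slope = slope * scale_of,
      year2_shift = rnorm(n, 0, year2_drought_sd) * scale_of,
      base = rnorm(n, 0, base_abundance_sd),
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("legacy_effects", "data.frame")
  out
}

#' Simulate compositional ASV counts from a planted dependence graph
#'
#' Latent log-abundances are drawn from the multivariate normal with the
#' planted precision matrix (logistic-normal model), shifted by per-taxon
#' legacy effects (`slope * swd_2020 / 100`, plus `year2_shift` for units
#' under the year-2 drought), pushed through a softmax to proportions, and
#' sampled as multinomial reads at fixed depth. Every sample's counts
#' therefore sum exactly to `depth`, mimicking a fixed sequencing effort,
#' and the conditional-dependence structure of the latent field matches the
#' planted graph -- the recovery target of neighbourhood selection.
#'
#' @param design design `data.frame` from [build_design()].
#' @param graph an [sample_interaction_graph()] result.
#' @param effects a [legacy_effects()] specification with one row per taxon
#'   of `graph`.
#' @param depth reads per sample (default 20000).
#' @param seed integer seed.
#' @param taxonomy optional taxonomy attached to the returned table
#'   (defaults to the kingdom labels in `effects`).
#' @return An [asv_table] whose rows are the design's `unit_id`s.
#' @export
simulate_counts <- function(design, graph, effects, depth = 20000, seed = 1,
                            taxonomy = NULL) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (depth <= 0) stop("`depth` must be positive")
  p <- graph$n_taxa
  if (nrow(effects) != p)
    stop("`effects` has ", nrow(effects), " taxa but `graph` has ", p)
  n <- nrow(design)
  sigma <- solve(graph$precision)
  cl <- chol(sigma)
  counts <- with_seed(child_seed(seed, 23L), {
    z <- matrix(rnorm(n * p), n, p) %*% cl
    mu <- outer(design$swd_2020 / 100, effects$slope) +
      outer(as.numeric(design$year2_treatment == "drought"),
            effects$year2_shift) +
      matrix(effects$base, n, p, byrow = TRUE)
    eta <- z + mu
    eta <- eta - apply(eta, 1L, max) # numerically safe softmax
    pr <- exp(eta)
    pr <- pr / rowSums(pr)
    t(apply(pr, 1L, function(q) rmultinom(1L, depth, q)[, 1L]))
  })
  rownames(counts) <- design$unit_id
  colnames(counts) <- effects$taxon_id
  if (is.null(taxonomy))
    taxonomy <- data.frame(taxon_id = effects$taxon_id,
                           kingdom = effects$kingdom,
                           stringsAsFactors = FALSE)
  asv_table(counts, taxonomy)
}

#' Simulate aboveground biomass with a threshold response to past drought
#'
#' Expected community aboveground biomass (g per mesocosm) is piecewise
#' linear in the year-1 soil water deficit with a breakpoint at
#' `threshold_swd` (default 76% SWD, where productivity thresholds occurred
#' in the year-1 gradient). The legacy slopes act on units under the year-2
#' drought treatment; year-2 control units sit at the baseline expectation,
#' so the resistance/recovery index of a droughted unit equals its expected
#' biomass over the baseline. Noise is multiplicative lognormal with
#' coefficient of variation `cv` (mean-preserving).
#'
#' @param design design `data.frame` from [build_design()].
#' @param threshold_swd breakpoint (% SWD), default 76.
#' @param pre_threshold_effect slope (g per % SWD) between the control SWD
#'   and the threshold, applied to year-2 droughted units.
#' @param post_threshold_effect slope (g per % SWD) above the threshold.
#' @param cv coefficient of variation of the lognormal noise (>= 0).
#' @param seed integer seed.
#' @param baseline expected biomass (g) of a control unit, default 10.
#' @param control_swd SWD of the year-1 control, default 20.
#' @return `data.frame` with `unit_id`, `aboveground_biomass`, and the
#'   noiseless `expected_biomass`.
#' @export
simulate_biomass <- function(design, threshold_swd = 76,
                             pre_threshold_effect = -0.02,
                             post_threshold_effect = -0.15,
                             cv = 0.1, seed = 1,
                             baseline = 10, control_swd = 20) {
  if (cv < 0) stop("`cv` must be non-negative")
  swd <- design$swd_2020
  droughted <- design$year2_treatment == "drought"
  mu <- rep(baseline, nrow(design))
  legacy <- pre_threshold_effect * (pmin(swd, threshold_swd) - control_swd) +
    post_threshold_effect * pmax(0, swd - threshold_swd)
  mu[droughted] <- mu[droughted] + legacy[droughted]
  if (any(mu <= 0))
    stop("expected biomass non-positive for some units; ",
         "weaken the slopes or raise `baseline`")
  y <- if (cv == 0) mu else with_seed(child_seed(seed, 24L), {
    s <- sqrt(log(1 + cv^2))
    mu * exp(rnorm(length(mu), -s^2 / 2, s))
  })
  data.frame(unit_id = design$unit_id, aboveground_biomass = y,
             expected_biomass = mu, stringsAsFactors = FALSE)
}

#' Simulate a complete drought-legacy experiment
#'
#' Convenience wrapper tying the generator together: builds the design,
#' taxonomy, planted interaction graph, legacy effects, ASV counts and
#' biomass from a single seed.
#'
#' @param seed integer seed driving every stage.
#' @param n_prokaryote,n_fungal taxa per kingdom.
#' @param depth reads per sample.
#' @param topology,density passed to [sample_interaction_graph()].
#' @param ... further arguments passed to [build_design()].
#' @return List with `design`, `taxonomy`, `graph`, `effects`, `counts`
#'   (an [asv_table]) and `biomass`.
#' @export
simulate_experiment <- function(seed = 1, n_prokaryote = 150, n_fungal = 80,
                                depth = 20000, topology = "band",
                                density = 0.02, ...) {
  design <- build_design(...)
  taxonomy <- synth_taxonomy(n_prokaryote, n_fungal, seed = seed)
  graph <- sample_interaction_graph(nrow(taxonomy), topology = topology,
                                    density = density, seed = seed)
  effects <- legacy_effects(taxonomy, seed = seed)
  counts <- simulate_counts(design, graph, effects, depth = depth,
                            seed = seed, taxonomy = taxonomy)
  biomass <- simulate_biomass(design, seed = seed)
  list(design = design, taxonomy = taxonomy, graph = graph,
       effects = effects, counts = counts, biomass = biomass)
}
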