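# Seeded synthetic-data generators: registries with configurable marginal
# distributions and paired rating sheets with a configurable inter-rater
# agreement probability.

check_probs <- function(p, what, tol = 1e-9) {
  p <- unlist(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    tpp_error("tpp_config_error", paste0(what, " must be probabilities in [0, 1]"))
  }
  p
}

check_dist <- function(p, levels, what, tol = 1e-9) {
  p <- check_probs(p, what)
  if (!all(levels %in% names(p))) {
    tpp_error("tpp_config_error",
              paste0(what, " must name: ", paste(levels, collapse = ", ")))
  }
  p <- p[levels]
  if (abs(sum(p) - 1) > tol) {
    tpp_error("tpp_config_error", paste0(what, " must sum to 1"))
  }
  p
}

#' Configuration for the synthetic generators
#'
#' Defaults encode the published pipeline landscape as the stated world:
#' phase marginals 0.601/0.062/0.169/0.129/0.039 (preclinical, I-IV),
#' product types 0.741/0.079/0.180, archetypes 0.461 new / 0.539 repurposed,
#' an active share of 0.382, and per-criterion exclusion-flag probabilities
#' proportioned to the 27/71 clinical exclusions. The inter-rater agreement
#' probability defaults to 0.8 (not reported in the source; see the methods
#' vignette).
#'
#' @param n_candidates Number of candidates to generate.
#' @param phase_probs,product_type_probs,archetype_probs,indication_probs
#'   Named marginal distributions (must sum to 1 within 1e-9).
#' @param active_prob Probability of being in active development.
#' @param flag_probs Named per-criterion probabilities over
#'   [eligibility_flags()] (independent Bernoulli, applied to clinical-phase
#'   candidates only).
#' @param level_probs Named distribution over [rating_levels()] used for
#'   rater A; restricted scales renormalize over their admissible subset.
#' @param agreement Probability in \[0,1\] that rater B copies rater A on a
#'   given parameter; otherwise B draws uniformly among the other admissible
#'   levels.
#' @param seed Integer seed; identical configs generate identical data.
#' @return Object of class `tpp_generator_config`.
#' @export
generator_config <- function(
    n_candidates = 100L,
    phase_probs = c(preclinical = 0.601, phase1 = 0.062, phase2 = 0.169,
                    phase3 = 0.129, phase4 = 0.039, marketed = 0),
    product_type_probs = c(drug = 0.741, biologic = 0.079,
                           dietary_supplement = 0.180),
    archetype_probs = c(new_entity = 0.461, repurposed = 0.539),
    indication_probs = c(prevention = 0.45, management = 0.53, both = 0.02),
    active_prob = 0.382,
    flag_probs = c(marketed_for_indication = 0.10,
                   who_recommended_or_routine = 0.155,
                   subgroup_recommended = 0.042,
                   halted_negative_outcomes = 0.028,
                   inferior_to_current = 0.028,
                   other_labour_indication = 0.028),
    level_probs = c(met_preferred = 0.30, met_minimum = 0.25,
                    partial_minimum = 0.20, not_met = 0.15, unknown = 0.10),
    agreement = 0.8,
    seed = 1L) {
  cfg <- structure(list(
    n_candidates = as.integer(n_candidates),
    phase_probs = check_dist(phase_probs, tpp_phases(), "phase_probs"),
    product_type_probs = check_dist(product_type_probs, tpp_product_types(),
                                    "product_type_probs"),
    archetype_probs = check_dist(archetype_probs, tpp_archetypes(),
                                 "archetype_probs"),
    indication_probs = check_dist(indication_probs, tpp_indications(),
                                  "indication_probs"),
    active_prob = check_probs(active_prob, "active_prob"),
    flag_probs = check_probs(flag_probs, "flag_probs"),
    level_probs = check_dist(level_probs, rating_levels(), "level_probs"),
    agreement = check_probs(agreement, "agreement"),
    seed = as.integer(seed)
  ), class = "tpp_generator_config")
  if (cfg$n_candidates < 0L) {
    tpp_error("tpp_config_error", "n_candidates must be non-negative")
  }
  if (!all(eligibility_flags() %in% names(cfg$flag_probs))) {
    tpp_error("tpp_config_error", "flag_probs must name all six criteria flags")
  }
  cfg
}

sample_levels_from <- function(dist) names(dist)[
  sample.int(length(dist), 1L, prob = dist)]

#' Generate a synthetic candidate registry
#'
#' Samples `n_candidates` candidates independently from the configured
#' marginals. Identical configs (including `seed`) produce identical
#' registries. Active candidates receive a last-update year in 2018-2021,
#' inactive ones 2000-2017 or (10% of them) an absent year.
#'
#' @param config A `tpp_generator_config`.
#' @return A validated `tpp_registry` (snapshot year 2021).
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "tpp_generator_config"))
  n <- config$n_candidates
  if (n == 0L) {
    return(registry(empty_candidate_frame(), snapshot_year = 2021L))
  }
  set.seed(config$seed)
  draw <- function(dist, n) {
    names(dist)[sample.int(length(dist), n, replace = TRUE, prob = dist)]
  }
  phase <- draw(config$phase_probs, n)
  active <- stats::runif(n) < config$active_prob
  year <- ifelse(active, sample(2018:2021, n, replace = TRUE),
                 sample(2000:2017, n, replace = TRUE))
  year[!active & stats::runif(n) < 0.10] <- NA_integer_
  subclasses <- c("Amino acid-peptide", "Tocolytic", "Vascular agents",
                  "Herbal", "Polyphenol", "Organic compound", "Unspecified")
  routes <- c("Oral", "Intravenous", "Vaginal", "Subcutaneous", "Unspecified")
  df <- data.frame(
    id = sprintf("syn-%05d", seq_len(n)),
    name = sprintf("synthetic candidate %d", seq_len(n)),
    indication = draw(config$indication_probs, n),
    phase = phase,
    product_type = draw(config$product_type_probs, n),
    archetype = draw(config$archetype_probs, n),
    last_update_year = as.integer(year),
    subclass = subclasses[sample.int(length(subclasses), n, replace = TRUE)],
    route = routes[sample.int(length(routes), n, replace = TRUE)],
    stringsAsFactors = FALSE
  )
  clinical <- df$phase %in% tpp_clinical_phases()
  for (f in eligibility_flags()) {
    df[[f]] <- clinical & (stats::runif(n) < config$flag_probs[[f]])
  }
  registry(df, snapshot_year = 2021L)
}

#' Generate paired rating sheets for a registry
#'
#' Emulates the dual independent rating workflow: for every candidate in a
#' rankable clinical phase (I-III), rater A draws each parameter from the
#' configured level distribution (restricted and renormalized to the
#' parameter's admissible levels) and rater B copies A with probability
#' `agreement`, otherwise draws uniformly among the other admissible levels.
#'
#' @param reg A `tpp_registry`.
#' @param config A `tpp_generator_config`.
#' @return List with `rater_a` and `rater_b`, parallel lists of
#'   `tpp_rating_sheet`s.
#' @export
generate_sheets <- function(reg, config) {
  stopifnot(inherits(config, "tpp_generator_config"))
  validate_registry(reg)
  # distinct stream from the registry draw, still fully determined by seed
  set.seed(config$seed + 104729L)
  df <- reg$candidates
  ids <- df$id[df$phase %in% tpp_rankable_phases()]
  params <- tpp_parameters()
  a_list <- vector("list", length(ids)); b_list <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    la <- character(length(params)); lb <- character(length(params))
    for (j in seq_along(params)) {
      adm <- admissible_levels(params[j])
      dist <- config$level_probs[adm] / sum(config$level_probs[adm])
      la[j] <- sample_levels_from(dist)
      lb[j] <- if (stats::runif(1) < config$agreement) la[j] else {
        others <- setdiff(adm, la[j])
        others[sample.int(length(others), 1L)]
      }
    }
    a_list[[k]] <- rating_sheet(ids[k], "rater_a", stats::setNames(la, params))
    b_list[[k]] <- rating_sheet(ids[k], "rater_b", stats::setNames(lb, params))
  }
  list(rater_a = a_list, rater_b = b_list)
}
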