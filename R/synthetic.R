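# Seeded synthetic-study generator: diseases, latent score sheets and noisy
# expert panels with the statistical structure the scoring pipeline assumes.

#' Configuration of the synthetic study generator
#'
#' The defaults emulate the reference elicitation: 52 diseases split across
#' the three categories as in the published category rankings (18 epizootic,
#' 15 food-producing, 19 zoonotic), expert panels of mean size 7, and a
#' positive public-health shift for zoonoses. Inter-expert disagreement
#' (`expert_noise_sd`) is illustrative — the reference study does not report
#' it.
#'
#' @param n_diseases Number of diseases (>= 1).
#' @param category_proportions Three non-negative proportions (epizootic,
#'   food_producing_complex, zoonotic) summing to 1; converted to counts by
#'   largest-remainder rounding so the allocation is deterministic.
#' @param panel_size_mean Mean panel size (Poisson draw per disease).
#' @param panel_size_min Floor on the panel size (>= 1).
#' @param expert_noise_sd Standard deviation of the Gaussian perturbation
#'   added to the latent score for each expert, rounded to an integer (halves
#'   away from zero) and clamped to the scale.
#' @param category_effects data.frame with columns `category`, `criterion`,
#'   `shift`: additive shifts applied to latent scores of the matching
#'   (category, criterion) cells before clamping. The default adds +2 to the
#'   public-health criterion for zoonoses.
#' @param availability_none_prob Probability that a gap area is flagged
#'   `"none"` (no product exists at all).
#' @param seed Integer master seed; every random draw derives from it.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_diseases = 52,
                             category_proportions = c(epizootic = 18,
                                                      food_producing_complex = 15,
                                                      zoonotic = 19) / 52,
                             panel_size_mean = 7,
                             panel_size_min = 1,
                             expert_noise_sd = 0.5,
                             category_effects = data.frame(
                               category = "zoonotic",
                               criterion = "Impact on public health \u2013 human health",
                               shift = 2,
                               stringsAsFactors = FALSE),
                             availability_none_prob = 0.1,
                             seed = 1L) {
  if (!is.numeric(n_diseases) || n_diseases < 1 || n_diseases != floor(n_diseases)) {
    abort_invalid("n_diseases must be a positive integer")
  }
  if (length(category_proportions) != 3L || any(category_proportions < 0) ||
      abs(sum(category_proportions) - 1) > 1e-9) {
    abort_invalid("category_proportions must be 3 non-negative values summing to 1")
  }
  if (is.null(names(category_proportions))) {
    names(category_proportions) <- disease_categories()
  }
  if (!setequal(names(category_proportions), disease_categories())) {
    abort_invalid("category_proportions must be named by the three disease categories")
  }
  if (!is.numeric(panel_size_mean) || panel_size_mean <= 0) {
    abort_invalid("panel_size_mean must be positive")
  }
  if (!is.numeric(panel_size_min) || panel_size_min < 1) {
    abort_invalid("panel_size_min must be >= 1")
  }
  if (!is.numeric(expert_noise_sd) || expert_noise_sd < 0) {
    abort_invalid("expert_noise_sd must be >= 0")
  }
  if (!is.data.frame(category_effects) ||
      !all(c("category", "criterion", "shift") %in% names(category_effects))) {
    abort_invalid("category_effects must have columns category, criterion, shift")
  }
  if (availability_none_prob < 0 || availability_none_prob > 1) {
    abort_invalid("availability_none_prob must be a probability")
  }
  structure(list(
    n_diseases = as.integer(n_diseases),
    category_proportions = category_proportions[disease_categories()],
    panel_size_mean = panel_size_mean,
    panel_size_min = as.integer(panel_size_min),
    expert_noise_sd = expert_noise_sd,
    category_effects = category_effects,
    availability_none_prob = availability_none_prob,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Deterministic largest-remainder apportionment of n among proportions p.
largest_remainder <- function(p, n) {
  quota <- p * n
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    # break remainder ties by position (first category wins)
    ord <- order(-(quota - counts), seq_along(p))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

# Per-disease substream seed: hashing (master seed, disease index) keeps each
# disease's draws independent of how many diseases follow it.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + as.double(i) * 7919) %% 2147483647)
}

draw_latent_sheet <- function(id, name, category, model, effects) {
  scores <- lapply(model$criteria, function(cr) {
    shift <- sum(effects$shift[effects$category == category &
                                 effects$criterion == cr$name])
    v <- sample(cr$scale$values, cr$n_levels, replace = TRUE) + shift
    stats::setNames(as.integer(clamp(v, min(cr$scale$values), cr$scale$max)),
                    cr$sub_criteria)
  })
  names(scores) <- criterion_names(model)
  scores
}

perturb_sheet <- function(latent, model, sd) {
  lapply(criterion_names(model), function(nm) {
    cr <- model$criteria[[nm]]
    eps <- round_half_away(stats::rnorm(cr$n_levels, 0, sd))
    stats::setNames(
      as.integer(clamp(latent[[nm]] + eps, min(cr$scale$values), cr$scale$max)),
      cr$sub_criteria)
  }) |> stats::setNames(criterion_names(model))
}

#' Generate a complete synthetic elicitation study
#'
#' For each disease: a category (deterministic largest-remainder allocation),
#' a latent integer score per sub-criterion of both models (uniform over the
#' scale, shifted by any matching category effect, clamped), a panel size
#' (Poisson around `panel_size_mean`, floored at `panel_size_min`) and one
#' noisy score sheet per expert (latent + rounded Gaussian noise, clamped to
#' the scale). Gap panels additionally draw one availability flag per area,
#' shared by the panel's experts. Expert roles are assigned cyclically
#' (diagnostic, epidemiology, industry, economics, other, ...), so panels of
#' four or more meet the coverage minimum.
#'
#' All draws for disease `i` come from a substream seeded by a hash of
#' `(config$seed, i)`, so the whole study is reproducible and adding diseases
#' does not perturb earlier ones.
#'
#' @param config A [generator_config()].
#' @param model Prioritisation [model_spec()].
#' @param gap_model Gap [model_spec()].
#' @return A list with `prioritisation` (list of [panel_scores()]), `gap`
#'   (list of [panel_scores()]) and `latent` (per disease:
#'   `disease_id`, `disease_name`, `category`, and the two latent
#'   [score_sheet()]s `prioritisation` and `gap`).
#' @export
generate_study <- function(config, model, gap_model) {
  if (!inherits(config, "generator_config")) abort_invalid("config must be a generator_config")
  if (!inherits(model, "model_spec") || model$model_kind != "prioritisation") {
    abort_invalid("model must be of kind 'prioritisation'")
  }
  if (!inherits(gap_model, "model_spec") || gap_model$model_kind != "gap") {
    abort_invalid("gap_model must be of kind 'gap'")
  }
  counts <- largest_remainder(config$category_proportions, config$n_diseases)
  categories <- rep(names(counts), counts)

  width <- max(3L, nchar(as.character(config$n_diseases)))
  prio_panels <- vector("list", config$n_diseases)
  gap_panels <- vector("list", config$n_diseases)
  latent <- vector("list", config$n_diseases)

  for (i in seq_len(config$n_diseases)) {
    id <- sprintf("d%0*d", width, i)
    nm <- sprintf("Disease %0*d", width, i)
    cat_i <- categories[i]
    set.seed(substream_seed(config$seed, i))

    lat_prio <- draw_latent_sheet(id, nm, cat_i, model, config$category_effects)
    lat_gap <- draw_latent_sheet(id, nm, cat_i, gap_model, config$category_effects)
    flags <- vapply(criterion_names(gap_model), function(nmc) {
      u <- stats::runif(1)
      p <- config$availability_none_prob
      if (u < p) "none" else if (u < p + (1 - p) / 2) "available" else "in_development"
    }, character(1))
    size <- max(config$panel_size_min, stats::rpois(1, config$panel_size_mean))
    roles <- rep(expert_roles(), length.out = size)

    make_panel <- function(mdl, lat, fl) {
      experts <- lapply(seq_len(size), function(j) {
        list(expert_id = sprintf("%s_e%02d", id, j),
             role = roles[j],
             sheet = score_sheet(id, nm, cat_i,
                                 perturb_sheet(lat, mdl, config$expert_noise_sd),
                                 availability_flags = fl))
      })
      panel_scores(id, experts)
    }

    prio_panels[[i]] <- make_panel(model, lat_prio, NULL)
    gap_panels[[i]] <- make_panel(gap_model, lat_gap, flags)
    latent[[i]] <- list(
      disease_id = id, disease_name = nm, category = cat_i,
      prioritisation = score_sheet(id, nm, cat_i, lat_prio),
      gap = score_sheet(id, nm, cat_i, lat_gap, availability_flags = flags))
  }
  list(prioritisation = prio_panels, gap = gap_panels, latent = latent)
}

#' Parameter-recovery report for aggregated synthetic panels
#'
#' Compares consensus score sheets against the latent truth they were
#' generated from: per-sub-criterion exact-match fractions, overall mean
#' absolute error, and the overlap of the top-`k` diseases by overall
#' prioritisation score.
#'
#' @param latent The `latent` element of [generate_study()] output.
#' @param aggregated List of consensus [score_sheet()]s (one per disease, as
#'   returned by [aggregate_panel()]), for the prioritisation model.
#' @param model The prioritisation [model_spec()].
#' @param k Size of the top set compared between latent and recovered
#'   rankings (default 10; `k = n` always gives overlap 1).
#' @return A list: `exact_match` (named fraction per
#'   `criterion || sub-criterion`), `mae`, `topk_overlap`, `k`.
#' @export
recovery_report <- function(latent, aggregated, model, k = 10) {
  lat_ids <- vapply(latent, `[[`, character(1), "disease_id")
  agg_ids <- vapply(aggregated, `[[`, character(1), "disease_id")
  if (!setequal(lat_ids, agg_ids)) abort_invalid("latent and aggregated disease sets differ")
  aggregated <- aggregated[match(lat_ids, agg_ids)]
  k <- min(k, length(lat_ids))

  keys <- unlist(lapply(model$criteria, function(cr) paste(cr$name, cr$sub_criteria, sep = " || ")))
  diffs <- vapply(seq_along(latent), function(i) {
    unlist(lapply(criterion_names(model), function(nm) {
      cr <- model$criteria[[nm]]
      aggregated[[i]]$scores[[nm]][cr$sub_criteria] -
        latent[[i]]$prioritisation$scores[[nm]][cr$sub_criteria]
    }), use.names = FALSE)
  }, numeric(length(keys)))
  diffs <- matrix(diffs, nrow = length(keys))

  lat_tot <- lapply(latent, function(l) disease_total(l$prioritisation, model))
  agg_tot <- lapply(aggregated, function(s) disease_total(s, model))
  top <- function(tt) utils::head(rank_diseases(tt, "overall")$disease_id, k)

  list(
    exact_match = stats::setNames(rowMeans(diffs == 0), keys),
    mae = mean(abs(diffs)),
    topk_overlap = length(intersect(top(lat_tot), top(agg_tot))) / k,
    k = k
  )
}
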