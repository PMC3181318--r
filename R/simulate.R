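# Synthetic-data generators with known causal structure.  Two levels:
#  * sample_rate_sem() draws rate-level observations directly from a
#    linear-Gaussian structural model (for engine calibration and recovery
#    studies);
#  * simulate_transition_dataset() emulates the field design itself --
#    transitions of ordered sites with transit times, six data categories,
#    a band-table fingerprint -- so the whole pipeline can be exercised
#    end to end.

#' Parameters of a linear-Gaussian structural model
#'
#' @param dag A [path_dag()].
#' @param edge_coefficients Named numeric vector (`"parent->child"`), one
#'   standardized coefficient per DAG edge.
#' @param residual_sd Named non-negative numeric vector, one standard
#'   deviation per node (for an exogenous node: its marginal SD).  A single
#'   unnamed value is recycled to all nodes.
#' @param n_samples Number of observations to draw.
#' @param seed Integer seed.
#' @return Object of class `sem_parameters`.
#' @export
sem_parameters <- function(dag, edge_coefficients, residual_sd = 1,
                           n_samples = 100, seed = 1) {
  stopifnot(inherits(dag, "path_dag"))
  lab <- edge_label(dag$edges$parent, dag$edges$child)
  if (length(edge_coefficients) == nrow(dag$edges) &&
      is.null(names(edge_coefficients))) {
    names(edge_coefficients) <- lab
  }
  unknown <- setdiff(names(edge_coefficients), lab)
  if (length(unknown)) {
    stop("coefficient(s) for edge(s) not in DAG: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(edge_coefficients), lab)) {
    stop("every DAG edge needs a coefficient", call. = FALSE)
  }
  if (length(residual_sd) == 1L && is.null(names(residual_sd))) {
    residual_sd <- stats::setNames(rep(residual_sd, length(dag$nodes)),
                                   dag$nodes)
  }
  if (!all(dag$nodes %in% names(residual_sd))) {
    stop("residual_sd must name every node", call. = FALSE)
  }
  if (any(residual_sd < 0)) stop("residual_sd must be non-negative",
                                 call. = FALSE)
  if (n_samples < 1) stop("n_samples must be positive", call. = FALSE)
  structure(list(dag = dag, edge_coefficients = edge_coefficients,
                 residual_sd = residual_sd[dag$nodes],
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "sem_parameters")
}

#' Draw rate-level observations from a structural model
#'
#' Nodes are generated in topological order: each equals the
#' coefficient-weighted sum of its parents plus Gaussian noise with its
#' residual SD; exogenous nodes are residual-only (standard normal under the
#' default unit residual SD).  A fixed seed yields identical output.
#'
#' @param params A [sem_parameters()].
#' @return Data frame with `n_samples` rows and one column per DAG node.
#' @export
sample_rate_sem <- function(params) {
  stopifnot(inherits(params, "sem_parameters"))
  dag <- params$dag
  order <- validate_dag(dag)
  n <- params$n_samples
  set.seed(params$seed)
  x <- matrix(0, n, length(dag$nodes),
              dimnames = list(NULL, dag$nodes))
  for (node in order) {
    mu <- 0
    for (pa in dag_parents(dag, node)) {
      mu <- mu + params$edge_coefficients[[edge_label(pa, node)]] * x[, pa]
    }
    x[, node] <- mu + stats::rnorm(n, sd = params$residual_sd[[node]])
  }
  as.data.frame(x)
}

#' Configuration of a community-level simulation
#'
#' Describes a synthetic field campaign: `n_transitions` environmental
#' transitions, each an ordered series of sites with transit times, sampled
#' on each of `dates`.  Resource variables drift monotonically along transit
#' time with a slope set by each transition's `gradient_intensity`;
#' downstream categories respond through `generating_dag`.  Community
#' composition is emitted as a band table whose behaviour depends on the
#' scenario: under `"adjustment"` a fixed set of band identities only
#' re-weights along the gradient (rearrangement), under `"replacement"` a
#' `turnover_fraction` of the head site's dominant bands is progressively
#' swapped for fresh identities downstream.
#'
#' @param n_transitions Number of transitions (default 13).
#' @param sites_per_transition Sites per transition (>= 2; default 4).
#' @param transit_times_h Transit times in hours, starting at 0 and strictly
#'   increasing, one per site (default `c(0, 6, 18, 36)`); recycled to all
#'   transitions.
#' @param gradient_intensity Per-transition non-negative scalar(s); default
#'   a geometric ladder from 0.2 to 5 so transitions differ strongly in
#'   gradient steepness.
#' @param scenario `"adjustment"` or `"replacement"`.
#' @param generating_dag [path_dag()] driving the downstream categories;
#'   default: the library model canonical for the scenario (B-DAG4 for
#'   adjustment, A-DAG4 for replacement).
#' @param edge_coefficient Coefficient placed on every generating edge
#'   (default 0.7).
#' @param n_bands_pool Size of the band identity pool (default 40).
#' @param n_bands_active Bands present per lane (default 15).
#' @param top_k Number of dominant bands subject to replacement (default 5).
#' @param turnover_fraction Fraction (0-1) of dominant bands replaced by the
#'   terminal site (replacement scenario only; default 0.5).
#' @param noise_sd Site-level noise SD applied to every category (default
#'   0.3).
#' @param dates Sampling-date labels (default June, July, August).
#' @param seed Integer master seed.
#' @return Object of class `community_sim_config`.
#' @export
community_sim_config <- function(n_transitions = 13, sites_per_transition = 4,
                                 transit_times_h = c(0, 6, 18, 36),
                                 gradient_intensity = NULL,
                                 scenario = c("adjustment", "replacement"),
                                 generating_dag = NULL, edge_coefficient = 0.7,
                                 n_bands_pool = 40, n_bands_active = 15,
                                 top_k = 5, turnover_fraction = 0.5,
                                 noise_sd = 0.3,
                                 dates = c("June", "July", "August"),
                                 seed = 1) {
  scenario <- match.arg(scenario)
  if (sites_per_transition < 2) {
    stop("sites_per_transition must be >= 2", call. = FALSE)
  }
  if (length(transit_times_h) != sites_per_transition) {
    stop("transit_times_h must have one value per site", call. = FALSE)
  }
  if (transit_times_h[1] != 0 || any(diff(transit_times_h) <= 0)) {
    stop("transit times must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  if (is.null(gradient_intensity)) {
    gradient_intensity <- exp(seq(log(0.2), log(5),
                                  length.out = n_transitions))
  }
  gradient_intensity <- rep_len(gradient_intensity, n_transitions)
  if (any(gradient_intensity < 0)) {
    stop("gradient_intensity must be non-negative", call. = FALSE)
  }
  if (turnover_fraction < 0 || turnover_fraction > 1) {
    stop("turnover_fraction must be in [0, 1]", call. = FALSE)
  }
  if (is.null(generating_dag)) {
    lib <- build_model_library()
    generating_dag <- if (scenario == "adjustment") lib[["B-DAG4"]] else
      lib[["A-DAG4"]]
  }
  stopifnot(inherits(generating_dag, "path_dag"))
  if (n_bands_pool < n_bands_active + top_k) {
    stop("n_bands_pool must cover the active set plus replacements",
         call. = FALSE)
  }
  structure(list(n_transitions = as.integer(n_transitions),
                 sites_per_transition = as.integer(sites_per_transition),
                 transit_times_h = as.numeric(transit_times_h),
                 gradient_intensity = gradient_intensity,
                 scenario = scenario, generating_dag = generating_dag,
                 edge_coefficient = edge_coefficient,
                 n_bands_pool = as.integer(n_bands_pool),
                 n_bands_active = as.integer(n_bands_active),
                 top_k = as.integer(top_k),
                 turnover_fraction = turnover_fraction,
                 noise_sd = noise_sd, dates = dates,
                 seed = as.integer(seed)),
            class = "community_sim_config")
}

#' Generating causal structure of a simulation
#'
#' @param config A [community_sim_config()].
#' @return The [path_dag()] the simulator drives its categories with; used
#'   as ground truth in recovery studies.
#' @export
scenario_truth <- function(config) {
  stopifnot(inherits(config, "community_sim_config"))
  config$generating_dag
}

# Per-category variable loadings (how many observed variables each latent
# category signal projects onto, with fixed loading patterns).
category_loadings <- list(
  RES = c(DOC = 1.0, TP = 0.8, TN = 0.6, CDOM = 0.9),
  SCC = c(HNA_FL1 = 1.0, HNA_SSC = 0.7, CTC_FL3 = 0.9),
  PS = c(spBP = 1.0, pct_HNA = 0.8, pct_CTC = 0.9, pct_intact = 0.6),
  BCM = c(BP = 1.0, BR = 0.8, BGR = 0.9)
)

#' Simulate a community-level transition dataset
#'
#' Produces, for every transition x date, site-level observations of the
#' six data categories driven by a known causal structure (see
#' [community_sim_config()]), as the raw tables the analysis chain reads:
#' category matrices (RES, SCC, PS, BCM, single-column BA), a band table
#' (BCC fingerprint), and the list of transition series.
#'
#' Mechanics: each transition x date draws a resource latent signal that
#' increases linearly with transit time at a slope proportional to the
#' transition's `gradient_intensity`; the remaining category latents follow
#' the generating DAG with coefficient `edge_coefficient` per edge plus
#' `noise_sd` Gaussian site noise.  Observed variables are fixed-loading
#' projections of their category latent (log-normal for the positive-valued
#' BA and BCM).  Band intensities are a softmax (concentration-parameterized
#' simplex) over the active band set whose log-weights drift with the BCC
#' latent; replacement additionally swaps dominant band identities (see
#' [community_sim_config()]).
#'
#' @param config A [community_sim_config()].
#' @return List with `transitions` (list of [transition_series()]),
#'   `categories` (named list of raw [category_matrix()]: RES, SCC, PS,
#'   BCM, BA), `bands` (intensity matrix), `metadata` (data frame:
#'   transition_id, date, site_id, order, transit_time_h), `config`.
#' @export
simulate_transition_dataset <- function(config) {
  stopifnot(inherits(config, "community_sim_config"))
  dag <- config$generating_dag
  order <- validate_dag(dag)
  coefs <- stats::setNames(rep(config$edge_coefficient, nrow(dag$edges)),
                           edge_label(dag$edges$parent, dag$edges$child))

  n_td <- config$n_transitions * length(config$dates)
  seeds <- derive_seeds(config$seed, n_td + 1L)
  band_seed <- seeds[n_td + 1L]

  # band pool scaffolding, shared across the campaign
  set.seed(band_seed)
  band_ids <- sprintf("B%02d", seq_len(config$n_bands_pool))
  n_sites <- config$sites_per_transition
  tt <- config$transit_times_h

  transitions <- list()
  meta <- list()
  cat_rows <- list(RES = list(), SCC = list(), PS = list(), BCM = list(),
                   BA = list())
  band_rows <- list()

  k <- 0L
  for (i in seq_len(config$n_transitions)) {
    for (d in config$dates) {
      k <- k + 1L
      set.seed(seeds[k])
      ids <- sprintf("T%02d_%s_S%d", i, d, seq_len(n_sites))
      ts <- transition_series(sprintf("T%02d", i), d, ids, tt)
      transitions[[k]] <- ts
      meta[[k]] <- data.frame(transition_id = ts$transition_id, date = d,
                              site_id = ids, order = seq_len(n_sites),
                              transit_time_h = tt,
                              stringsAsFactors = FALSE)

      # latent category signals along the transition
      g <- config$gradient_intensity[i]
      latent <- matrix(0, n_sites, length(dag$nodes),
                       dimnames = list(ids, dag$nodes))
      for (node in order) {
        if (node == "RES") {
          drift <- g * tt / max(tt)
          latent[, node] <- drift + config$noise_sd * stats::rnorm(n_sites)
        } else {
          mu <- rep(0, n_sites)
          for (pa in dag_parents(dag, node)) {
            mu <- mu + coefs[[edge_label(pa, node)]] * latent[, pa]
          }
          latent[, node] <- mu + config$noise_sd * stats::rnorm(n_sites)
        }
      }

      # observed variables per category
      for (cat in c("RES", "SCC", "PS", "BCM")) {
        lo <- category_loadings[[cat]]
        obs <- outer(latent[, cat], lo) +
          config$noise_sd * matrix(stats::rnorm(n_sites * length(lo)),
                                   n_sites)
        colnames(obs) <- names(lo)
        rownames(obs) <- ids
        if (cat == "BCM") obs <- 10 * exp(0.5 * obs)  # positive rates
        cat_rows[[cat]][[k]] <- obs
      }
      ba <- 2e6 * exp(0.4 * latent[, "BA"] +
                        0.1 * config$noise_sd * stats::rnorm(n_sites))
      cat_rows[["BA"]][[k]] <- matrix(ba, ncol = 1,
                                      dimnames = list(ids, "BA"))

      # band table for this transition x date
      band_rows[[k]] <- simulate_band_block(config, latent[, "BCC"], ids,
                                            band_ids)
    }
  }

  bands <- do.call(rbind, band_rows)
  categories <- list(
    RES = category_matrix(do.call(rbind, cat_rows$RES), "RES"),
    SCC = category_matrix(do.call(rbind, cat_rows$SCC), "SCC"),
    PS = category_matrix(do.call(rbind, cat_rows$PS), "PS"),
    BCM = category_matrix(do.call(rbind, cat_rows$BCM), "BCM"),
    BA = category_matrix(do.call(rbind, cat_rows$BA), "BA")
  )
  list(transitions = transitions, categories = categories, bands = bands,
       metadata = do.call(rbind, meta), config = config)
}

# One transition x date block of band intensities.  Adjustment: fixed active
# identity set, log-weights drift with the BCC latent (softmax keeps every
# active band positive, so presence-absence never changes).  Replacement:
# downstream sites progressively swap the head's dominant (top_k) band
# identities for fresh pool bands; swapped-out bands drop to zero intensity.
simulate_band_block <- function(config, bcc_latent, ids, band_ids) {
  n_sites <- length(ids)
  n_pool <- config$n_bands_pool
  active <- sort(sample.int(n_pool, config$n_bands_active))
  w0 <- stats::rnorm(config$n_bands_active, sd = 1.2)   # uneven base lane
  drift <- stats::rnorm(config$n_bands_active)          # response direction

  block <- matrix(0, n_sites, n_pool, dimnames = list(ids, band_ids))
  weights <- function(s) {
    w <- w0 + 0.8 * s * drift
    exp(w - max(w)) / sum(exp(w - max(w)))
  }

  if (config$scenario == "adjustment" || config$turnover_fraction == 0) {
    for (j in seq_len(n_sites)) {
      block[j, active] <- 1000 * weights(bcc_latent[j])
    }
    return(block)
  }

  # replacement: head lane first, then cumulative identity swaps
  head_w <- weights(bcc_latent[1])
  block[1, active] <- 1000 * head_w
  dominant <- active[order(head_w, decreasing = TRUE)][seq_len(config$top_k)]
  fresh <- sample(setdiff(seq_len(n_pool), active))
  for (j in 2:n_sites) {
    m <- ceiling(config$turnover_fraction * config$top_k *
                   (j - 1) / (n_sites - 1))
    act_j <- active
    if (m > 0) {
      out <- dominant[seq_len(m)]
      act_j[match(out, act_j)] <- fresh[seq_len(m)]
    }
    block[j, act_j] <- 1000 * weights(bcc_latent[j])
  }
  block
}
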