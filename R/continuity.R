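#' Monte-Carlo probability of the exclusivity statistic
#'
#' Approximates the probability that at least `k` of the ancient lineages
#' form a clade exclusive of all modern lineages, by simulating `reps`
#' independent genealogies under `config` and counting the replicates on
#' which the statistic holds. The estimator is the raw proportion
#' `hits / reps` by default; the `(hits + 1) / (reps + 1)` variant is
#' available via `estimator = "add_one"`.
#'
#' @param config a `continuity_config` from [validate_config()].
#' @param k exclusivity threshold (default 8).
#' @param reps number of simulated genealogies (default 10000).
#' @param seed non-negative integer seed.
#' @param stream_offset first replicate substream index; grid scans give each
#'   grid point a disjoint block of substreams.
#' @param statistic `"pooled"` (default) or `"single"`, see
#'   [pooled_exclusive_ancient_count()] and [max_exclusive_ancient_clade()].
#' @param estimator `"raw"` or `"add_one"`.
#' @return A `monte_carlo_estimate`: `p_hat`, `hits`, `reps`,
#'   `standard_error` (binomial, `sqrt(p(1-p)/reps)`), `k`, `seed`,
#'   `stream_offset` and the configuration fingerprint.
#' @examples
#' cfg <- validate_config(constant_model(500), sampling_scheme(20, 5, 1000))
#' estimate_probability(cfg, k = 3, reps = 200, seed = 1)
#' @export
estimate_probability <- function(config, k = 8, reps = 10000, seed = 1,
                                 stream_offset = 0,
                                 statistic = c("pooled", "single"),
                                 estimator = c("raw", "add_one")) {
  stopifnot(inherits(config, "continuity_config"), reps >= 1)
  estimator <- match.arg(estimator)
  statistic <- match.arg(statistic)
  n_anc <- config$sampling$ancient_count
  if (!is.numeric(k) || k != round(k) || k < 1 || k > n_anc)
    stop("k must be an integer between 1 and ancient_count (", n_anc, ")")
  ind <- sim_stat_batch_cpp(config$cpp, as.integer(reps), check_seed(seed),
                            stream_offset, as.integer(k),
                            match(statistic, c("single", "pooled")) - 1L)
  hits <- sum(ind)
  p <- if (estimator == "raw") hits / reps else (hits + 1) / (reps + 1)
  structure(list(p_hat = p, hits = hits, reps = as.integer(reps),
                 k = as.integer(k),
                 standard_error = sqrt(p * (1 - p) / reps),
                 seed = seed, stream_offset = stream_offset,
                 statistic = statistic, estimator = estimator,
                 fingerprint = config$fingerprint),
            class = "monte_carlo_estimate")
}

#' @export
print.monte_carlo_estimate <- function(x, ...) {
  cat(sprintf("<monte_carlo_estimate> p_hat = %.4f (SE %.4f, %d/%d reps, k = %d)\n",
              x$p_hat, x$standard_error, x$hits, x$reps, x$k))
  invisible(x)
}

#' Largest effective size not rejected by the continuity test
#'
#' Scans a grid of effective sizes (constant model: `ne`; expansion model:
#' the initial size `ne_initial`, with the present size and growth onset
#' fixed), estimating the exclusivity probability at each point, and reports
#' the largest scanned value whose estimate is still `>= alpha` — the
#' boundary of the region rejected at level `alpha`. The probability is
#' monotone non-increasing in the scanned size, so every value above the
#' threshold is rejected.
#'
#' @param model_family `"constant"` or `"expansion"`.
#' @param grid increasing vector of sizes to scan.
#' @param alpha significance level (default 0.05).
#' @param reps replicates per grid point (default 10000).
#' @param seed non-negative integer seed; grid point `i` uses replicate
#'   substreams `(i-1)*reps .. i*reps - 1`.
#' @param sampling,timescale sampling scheme and generation time.
#' @param k exclusivity threshold.
#' @param ne_present,growth_start_generations expansion-model constants.
#' @return A `threshold_scan`: the `threshold` (NA if every grid point was
#'   rejected), a `boundary` flag (`"interior"`, `"below_range"` if all
#'   rejected, `"above_range"` if none rejected) and the full
#'   `(parameter, p_hat, se)` trace.
#' @export
rejection_threshold <- function(model_family = c("constant", "expansion"),
                                grid, alpha = 0.05, reps = 10000, seed = 1,
                                sampling = sampling_scheme(),
                                timescale = time_scale(), k = 8,
                                statistic = c("pooled", "single"),
                                ne_present = 15000,
                                growth_start_generations = 200) {
  model_family <- match.arg(model_family)
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(grid), length(grid) >= 1, all(grid > 0),
            alpha > 0, alpha < 1)
  grid <- sort(unique(grid))
  p <- se <- numeric(length(grid))
  for (i in seq_along(grid)) {
    model <- if (model_family == "constant") {
      constant_model(grid[i])
    } else {
      expansion_model(ne_initial = grid[i], ne_present = ne_present,
                      growth_start_generations = growth_start_generations)
    }
    cfg <- validate_config(model, sampling, timescale)
    est <- estimate_probability(cfg, k = k, reps = reps, seed = seed,
                                stream_offset = (i - 1) * reps,
                                statistic = statistic)
    p[i] <- est$p_hat
    se[i] <- est$standard_error
  }
  keep <- which(p >= alpha)
  threshold <- if (length(keep)) grid[max(keep)] else NA_real_
  boundary <- if (!length(keep)) "below_range"
              else if (max(keep) == length(grid)) "above_range"
              else "interior"
  structure(list(model_family = model_family,
                 parameter = if (model_family == "constant") "ne" else "ne_initial",
                 trace = data.frame(parameter = grid, p_hat = p, se = se),
                 threshold = threshold, boundary = boundary,
                 alpha = alpha, reps = as.integer(reps), k = as.integer(k),
                 statistic = statistic, seed = seed),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("<threshold_scan>", x$model_family, "model,", x$parameter, "scan\n")
  cat("  largest non-rejected value at alpha =", x$alpha, ":",
      x$threshold, paste0("(", x$boundary, ")"), "\n")
  cat("  grid:", min(x$trace$parameter), "..", max(x$trace$parameter),
      "in", nrow(x$trace), "points,", x$reps, "reps each\n")
  invisible(x)
}

#' 95% upper limit on the admixture proportion
#'
#' Under the isolation-admixture model at a given effective size and
#' generation time, scans the admixture proportion `c` over `c_grid` and
#' reports the largest value whose exclusivity probability is still
#' `>= alpha` — the upper limit on the contribution of the ancient (New
#' World) population to the modern gene pool.
#'
#' @inheritParams rejection_threshold
#' @param ne haploid effective size of each deme.
#' @param c_grid increasing grid of admixture proportions in `[0, 1]`
#'   (default step 0.01).
#' @param split_years,bottleneck_start_years,join_years,bottleneck_factor
#'   isolation-admixture event parameters (package defaults are the model's
#'   standard calibration).
#' @param new_world_size `"equal"` or `"proportional"` New World deme size.
#' @return An `admixture_limit`: `c_limit`, a `boundary` flag and the
#'   `(c, p_hat, se)` trace.
#' @export
admixture_upper_limit <- function(ne, timescale = time_scale(), alpha = 0.05,
                                  c_grid = seq(0, 1, by = 0.01), reps = 10000,
                                  seed = 1, sampling = sampling_scheme(),
                                  k = 8, statistic = c("pooled", "single"),
                                  split_years = 400,
                                  bottleneck_start_years = 13000,
                                  join_years = 14000, bottleneck_factor = 10,
                                  new_world_size = "equal") {
  stopifnot(is.numeric(c_grid), all(c_grid >= 0 & c_grid <= 1),
            alpha > 0, alpha < 1)
  statistic <- match.arg(statistic)
  c_grid <- sort(unique(c_grid))
  p <- se <- numeric(length(c_grid))
  for (i in seq_along(c_grid)) {
    model <- admixture_model(ne = ne, c = c_grid[i], split_years = split_years,
                             bottleneck_start_years = bottleneck_start_years,
                             join_years = join_years,
                             bottleneck_factor = bottleneck_factor,
                             new_world_size = new_world_size)
    cfg <- validate_config(model, sampling, timescale)
    est <- estimate_probability(cfg, k = k, reps = reps, seed = seed,
                                stream_offset = (i - 1) * reps,
                                statistic = statistic)
    p[i] <- est$p_hat
    se[i] <- est$standard_error
  }
  keep <- which(p >= alpha)
  c_limit <- if (length(keep)) c_grid[max(keep)] else NA_real_
  boundary <- if (!length(keep)) "below_range"
              else if (max(keep) == length(c_grid)) "above_range"
              else "interior"
  structure(list(ne = ne,
                 generation_time_years = timescale$generation_time_years,
                 trace = data.frame(c = c_grid, p_hat = p, se = se),
                 c_limit = c_limit, boundary = boundary, alpha = alpha,
                 reps = as.integer(reps), k = as.integer(k),
                 statistic = statistic, seed = seed),
            class = "admixture_limit")
}

#' @export
print.admixture_limit <- function(x, ...) {
  cat("<admixture_limit> Ne =", x$ne, ", generation time",
      x$generation_time_years, "years\n")
  cat("  ", 100 * (1 - x$alpha), "% upper limit on c: ", x$c_limit,
      " (", x$boundary, ")\n", sep = "")
  invisible(x)
}

#' Admixture limit curve over effective sizes and generation times
#'
#' Evaluates [admixture_upper_limit()] over the product of an effective-size
#' grid and a set of generation times, yielding a plot-ready table of 95%
#' limits (the solid/dashed curves of the published figure correspond to
#' generation times of 2 and 3 years).
#'
#' @inheritParams admixture_upper_limit
#' @param ne_grid vector of effective sizes.
#' @param timescales list of [time_scale()] objects.
#' @return An `admixture_limit_curve`: a data frame with columns `ne`,
#'   `generation_time_years`, `c_limit`, `boundary`, plus the per-point
#'   scans in `attr(, "scans")`.
#' @export
limit_curve <- function(ne_grid, timescales = list(time_scale(2), time_scale(3)),
                        alpha = 0.05, c_grid = seq(0, 1, by = 0.01),
                        reps = 10000, seed = 1, sampling = sampling_scheme(),
                        k = 8, ...) {
  stopifnot(length(ne_grid) >= 1, length(timescales) >= 1)
  rows <- list()
  scans <- list()
  idx <- 0L
  for (ts in timescales) {
    for (ne in ne_grid) {
      idx <- idx + 1L
      lim <- admixture_upper_limit(ne = ne, timescale = ts, alpha = alpha,
                                   c_grid = c_grid, reps = reps,
                                   seed = seed + idx, sampling = sampling,
                                   k = k, ...)
      rows[[idx]] <- data.frame(ne = ne,
                                generation_time_years = ts$generation_time_years,
                                c_limit = lim$c_limit,
                                boundary = lim$boundary)
      scans[[idx]] <- lim
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scans") <- scans
  class(out) <- c("admixture_limit_curve", "data.frame")
  out
}
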