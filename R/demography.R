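#' Generation-time scale
#'
#' Converts calendar time to coalescent time. Dogs are usually assigned a
#' generation time of 2 or 3 years; both values are carried through the
#' continuity analyses.
#'
#' @param generation_time_years positive number of years per generation.
#' @return An object of class `time_scale`.
#' @examples
#' time_scale(2)
#' @export
time_scale <- function(generation_time_years = 2) {
  if (!is.numeric(generation_time_years) || length(generation_time_years) != 1 ||
      !is.finite(generation_time_years) || generation_time_years <= 0)
    stop("generation_time_years must be a single positive number")
  structure(list(generation_time_years = generation_time_years),
            class = "time_scale")
}

#' Heterochronous sampling scheme
#'
#' Two temporal samples: `modern_count` lineages at the present and
#' `ancient_count` lineages `ancient_age_years` before present. The defaults
#' (299 modern, 13 ancient at 1000 years) describe the Latin American dog
#' mtDNA samples the continuity tests were designed around.
#'
#' @param modern_count positive integer, lineages sampled at present.
#' @param ancient_count non-negative integer, lineages sampled in the past.
#' @param ancient_age_years non-negative age of the ancient sample in years.
#' @param ancient_deme deme the ancient sample is drawn from under the
#'   isolation-admixture model; only `"new_world"` is supported.
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(modern_count = 299, ancient_count = 13,
                            ancient_age_years = 1000,
                            ancient_deme = "new_world") {
  if (!is.numeric(modern_count) || modern_count < 1 ||
      modern_count != round(modern_count))
    stop("modern_count must be a positive integer")
  if (!is.numeric(ancient_count) || ancient_count < 0 ||
      ancient_count != round(ancient_count))
    stop("ancient_count must be a non-negative integer")
  if (!is.numeric(ancient_age_years) || ancient_age_years < 0)
    stop("ancient_age_years must be non-negative")
  ancient_deme <- match.arg(ancient_deme, "new_world")
  structure(list(modern_count = as.integer(modern_count),
                 ancient_count = as.integer(ancient_count),
                 ancient_age_years = ancient_age_years,
                 ancient_deme = ancient_deme),
            class = "sampling_scheme")
}

#' Convert calendar years to generations
#'
#' Rounds to the nearest integer generation; event times are compared on the
#' generation scale throughout the package.
#'
#' @param years non-negative number of calendar years.
#' @param timescale a [time_scale()].
#' @return Non-negative integer number of generations.
#' @examples
#' years_to_generations(1000, time_scale(2)) # 500
#' @export
years_to_generations <- function(years, timescale = time_scale()) {
  stopifnot(inherits(timescale, "time_scale"))
  if (!is.numeric(years) || any(!is.finite(years)) || any(years < 0))
    stop("years must be non-negative and finite")
  as.integer(round(years / timescale$generation_time_years))
}

new_demographic_model <- function(variant, fields) {
  structure(c(list(variant = variant), fields),
            class = c(paste0(variant, "_model"), "demographic_model"))
}

#' Demographic models
#'
#' Three backward-time demographies for a haploid (mitochondrial) population:
#'
#' * `constant_model(ne)` — a single population of constant size `ne`.
#' * `expansion_model()` — a single population of present size `ne_present`
#'   that began growing exponentially `growth_start_generations` ago from an
#'   initial size `ne_initial` (backward in time it shrinks to `ne_initial`
#'   and stays there).
#' * `admixture_model()` — the isolation-admixture model: a single present-day
#'   population whose lineages are assigned, `split_years` ago, to an isolated
#'   New World deme with probability `c` (else the Old World deme); the New
#'   World deme undergoes a `bottleneck_factor`-fold size reduction between
#'   `bottleneck_start_years` and `join_years`, when the demes merge back into
#'   a single ancestral population. The ancient sample is drawn from the New
#'   World deme. By default both demes have size `ne`; with
#'   `new_world_size = "proportional"` the New World deme has size `c * ne`.
#'
#' All sizes are haploid effective sizes (females for mtDNA).
#'
#' @param ne,ne_present,ne_initial positive haploid effective sizes.
#' @param growth_start_generations positive integer; the expansion model's
#'   growth onset, already on the generation scale.
#' @param c admixture proportion in `[0, 1]`: the probability that a lineage
#'   is assigned to the New World deme at the split.
#' @param split_years,bottleneck_start_years,join_years event ages in years.
#' @param bottleneck_factor positive factor by which the New World deme
#'   shrinks during the bottleneck (10 = tenfold reduction).
#' @param new_world_size `"equal"` (New World deme size `ne`) or
#'   `"proportional"` (`c * ne`).
#' @return An object of class `demographic_model`.
#' @examples
#' constant_model(3000)
#' expansion_model(ne_initial = 2100)
#' admixture_model(ne = 40000, c = 0.05)
#' @name demographic_model
NULL

#' @rdname demographic_model
#' @export
constant_model <- function(ne) {
  if (!is.numeric(ne) || length(ne) != 1 || !is.finite(ne) || ne <= 0)
    stop("ne must be a single positive number")
  new_demographic_model("constant", list(ne = ne))
}

#' @rdname demographic_model
#' @export
expansion_model <- function(ne_initial, ne_present = 15000,
                            growth_start_generations = 200) {
  if (!is.numeric(ne_initial) || ne_initial <= 0 || !is.finite(ne_initial))
    stop("ne_initial must be positive")
  if (!is.numeric(ne_present) || ne_present <= 0 || !is.finite(ne_present))
    stop("ne_present must be positive")
  if (!is.numeric(growth_start_generations) || growth_start_generations <= 0)
    stop("growth_start_generations must be positive")
  new_demographic_model("expansion",
                        list(ne_present = ne_present, ne_initial = ne_initial,
                             growth_start_generations = growth_start_generations))
}

#' @rdname demographic_model
#' @export
admixture_model <- function(ne, c, split_years = 400,
                            bottleneck_start_years = 13000,
                            join_years = 14000, bottleneck_factor = 10,
                            new_world_size = c("equal", "proportional")) {
  if (!is.numeric(ne) || ne <= 0 || !is.finite(ne))
    stop("ne must be positive")
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c < 0 || c > 1)
    stop("admixture proportion c must lie in [0, 1]")
  if (bottleneck_factor <= 0) stop("bottleneck_factor must be positive")
  new_world_size <- match.arg(new_world_size)
  if (new_world_size == "proportional" && c == 0)
    stop("proportional New World deme size requires c > 0")
  if (split_years <= 0 || bottleneck_start_years <= 0 || join_years <= 0)
    stop("event ages must be positive")
  new_demographic_model("isolation_admixture",
                        list(ne = ne, c = c, split_years = split_years,
                             bottleneck_start_years = bottleneck_start_years,
                             join_years = join_years,
                             bottleneck_factor = bottleneck_factor,
                             new_world_size = new_world_size))
}

#' Population size at a time in the past
#'
#' Evaluates the (haploid) deme size trajectory of a demographic model at
#' `t` generations before present.
#'
#' @param model a [demographic_model].
#' @param t non-negative time in generations before present.
#' @param deme `"main"` for the single population (and, under the
#'   isolation-admixture model, for the merged present-day population, the Old
#'   World deme and the merged ancestral population, all of size `ne`), or
#'   `"new_world"` for the New World deme, which exists only between the split
#'   and the join.
#' @param timescale a [time_scale()] used to place the admixture model's
#'   year-denominated events on the generation scale.
#' @return Positive deme size.
#' @examples
#' size_at(expansion_model(ne_initial = 2100), 0)    # 15000
#' size_at(expansion_model(ne_initial = 2100), 200)  # 2100
#' @export
size_at <- function(model, t, deme = c("main", "new_world"),
                    timescale = time_scale()) {
  stopifnot(inherits(model, "demographic_model"))
  deme <- match.arg(deme)
  if (!is.numeric(t) || any(t < 0)) stop("t must be non-negative")
  if (model$variant != "isolation_admixture" && deme == "new_world")
    stop("only the isolation-admixture model has a New World deme")
  switch(model$variant,
    constant = rep_len(model$ne, length(t)),
    expansion = {
      r <- log(model$ne_present / model$ne_initial) / model$growth_start_generations
      ifelse(t <= model$growth_start_generations,
             model$ne_present * exp(-r * t), model$ne_initial)
    },
    isolation_admixture = {
      g_split <- years_to_generations(model$split_years, timescale)
      g_bot <- years_to_generations(model$bottleneck_start_years, timescale)
      g_join <- years_to_generations(model$join_years, timescale)
      if (deme == "main") {
        rep_len(model$ne, length(t))
      } else {
        if (any(t < g_split | t >= g_join))
          stop("New World deme only exists between the split (", g_split,
               ") and the join (", g_join, ") generations before present")
        nw <- if (model$new_world_size == "proportional") model$c * model$ne else model$ne
        ifelse(t >= g_bot, nw / model$bottleneck_factor, nw)
      }
    })
}

#' Validate a model/sampling/timescale configuration
#'
#' Converts every event age to generations, checks all model invariants
#' (positive sizes, `c` in `[0, 1]`, event-time ordering
#' split < ancient sample age <= bottleneck start < join) and freezes the
#' result into a simulation-ready configuration.
#'
#' @param model a [demographic_model].
#' @param sampling a [sampling_scheme()].
#' @param timescale a [time_scale()].
#' @return An object of class `continuity_config` holding the original pieces,
#'   all event times in generations, and a plain-text fingerprint.
#' @examples
#' validate_config(admixture_model(40000, c = 0.05))
#' @export
validate_config <- function(model, sampling = sampling_scheme(),
                            timescale = time_scale()) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(sampling, "sampling_scheme"),
            inherits(timescale, "time_scale"))
  t_anc <- years_to_generations(sampling$ancient_age_years, timescale)
  cpp <- list(variant = 0L, ne = 1, ne_present = 1, ne_initial = 1,
              t_growth = 1, c = 0, t_split = 1, t_bottle = 2, t_join = 3,
              bottleneck_factor = 1, proportional_nw = FALSE,
              n_modern = sampling$modern_count,
              n_ancient = sampling$ancient_count,
              t_anc = as.numeric(t_anc))
  if (model$variant == "constant") {
    cpp$variant <- 0L
    cpp$ne <- model$ne
  } else if (model$variant == "expansion") {
    cpp$variant <- 1L
    cpp$ne_present <- model$ne_present
    cpp$ne_initial <- model$ne_initial
    cpp$t_growth <- model$growth_start_generations
  } else {
    cpp$variant <- 2L
    cpp$ne <- model$ne
    cpp$c <- model$c
    cpp$t_split <- as.numeric(years_to_generations(model$split_years, timescale))
    cpp$t_bottle <- as.numeric(years_to_generations(model$bottleneck_start_years, timescale))
    cpp$t_join <- as.numeric(years_to_generations(model$join_years, timescale))
    cpp$bottleneck_factor <- model$bottleneck_factor
    cpp$proportional_nw <- model$new_world_size == "proportional"
    if (!(cpp$t_split < cpp$t_anc))
      stop("invariant violated: split (", cpp$t_split,
           " generations) must precede the ancient sampling age (",
           cpp$t_anc, " generations)")
    if (!(cpp$t_anc <= cpp$t_bottle))
      stop("invariant violated: ancient sampling age (", cpp$t_anc,
           ") must not postdate the bottleneck start (", cpp$t_bottle, ")")
    if (!(cpp$t_bottle < cpp$t_join))
      stop("invariant violated: bottleneck start (", cpp$t_bottle,
           ") must precede the join (", cpp$t_join, ")")
  }
  fp <- paste(vapply(cpp, function(x) format(x, digits = 15), ""),
              collapse = ";")
  fp <- paste0(model$variant, ";g=", timescale$generation_time_years, ";", fp)
  structure(list(model = model, sampling = sampling, timescale = timescale,
                 cpp = cpp, fingerprint = fp),
            class = "continuity_config")
}

#' @export
print.continuity_config <- function(x, ...) {
  cat("<continuity_config>", x$model$variant, "model\n")
  cat("  sampling:", x$sampling$modern_count, "modern +",
      x$sampling$ancient_count, "ancient at", x$cpp$t_anc, "generations\n")
  cat("  generation time:", x$timescale$generation_time_years, "years\n")
  pars <- x$cpp[!names(x$cpp) %in%
                  c("variant", "n_modern", "n_ancient", "t_anc")]
  if (x$cpp$variant == 0L) pars <- pars["ne"]
  if (x$cpp$variant == 1L) pars <- pars[c("ne_present", "ne_initial", "t_growth")]
  if (x$cpp$variant == 2L)
    pars <- pars[c("ne", "c", "t_split", "t_bottle", "t_join",
                   "bottleneck_factor")]
  cat("  ", paste(names(pars), unlist(pars), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a model configuration from a YAML file
#'
#' The file must define `variant` (one of `constant`, `expansion`,
#' `isolation_admixture`) together with exactly the parameters that variant
#' accepts, and may define `sampling:` (`modern_count`, `ancient_count`,
#' `ancient_age_years`) and `generation_time_years`. Unknown or mismatched
#' keys are rejected. All defaults equal the package defaults.
#'
#' @param path path to a YAML file.
#' @return A validated `continuity_config`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$variant)) stop("config must name a 'variant'")
  variant <- match.arg(y$variant,
                       c("constant", "expansion", "isolation_admixture"))
  allowed <- switch(variant,
    constant = "ne",
    expansion = c("ne_initial", "ne_present", "growth_start_generations"),
    isolation_admixture = c("ne", "c", "split_years", "bottleneck_start_years",
                            "join_years", "bottleneck_factor", "new_world_size"))
  pars <- y[setdiff(names(y), c("variant", "sampling", "generation_time_years"))]
  bad <- setdiff(names(pars), allowed)
  if (length(bad))
    stop("parameter/variant mismatch: ", paste(bad, collapse = ", "),
         " not valid for the ", variant, " model")
  model <- do.call(switch(variant, constant = constant_model,
                          expansion = expansion_model,
                          isolation_admixture = admixture_model), pars)
  samp <- do.call(sampling_scheme, y$sampling %||% list())
  ts <- time_scale(y$generation_time_years %||% 2)
  validate_config(model, samp, ts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed) || seed < 0 || seed >= 2^31)
    stop("seed must be a single non-negative integer below 2^31")
  as.numeric(seed)
}
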