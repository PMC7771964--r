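#' Parameters for the Moran ancestry-proportion simulator
#'
#' The simulator tracks a single heritable quantity per individual -- the
#' genome-wide Amerindigenous (AI) ancestry proportion -- in a Moran model
#' with overlapping generations: each elementary step replaces one
#' individual, and N steps correspond to one generation. Four forces act on
#' the population:
#'
#' * **Assortative mating** (`AM` in \[0,1\]): with probability `AM` the
#'   second parent is the first parent's nearest neighbour when individuals
#'   are sorted by ancestry proportion; with probability `1 - AM` it is a
#'   uniformly random other individual. `AM = 0` is random mating; `AM = 1`
#'   pairs nearest neighbours always.
#' * **Ancestry-based fecundity differences** (`FAI >= 0`): the first
#'   parent is the individual at ancestry-rank quantile `q`, where `q` is
#'   drawn from a Beta law controlled by `FAI` (see
#'   [fecundity_quantile()]). `FAI = 0` selects uniformly; larger `FAI`
#'   favours high-AI parents.
#' * **Migration** (`M` in \[0,1\], `mAI` in \[0,1\]): with probability `M`
#'   the incoming individual is a migrant whose ancestry is drawn from a
#'   Beta distribution with mean `mAI` and concentration
#'   `migrant_concentration` (`Inf` = point mass at `mAI`).
#' * **Exponential growth** (`growth_rate` per generation): realized by
#'   scheduled birth-without-death events spread uniformly within each
#'   generation, so that population size tracks `N0 * exp(growth_rate * t)`
#'   while a generation remains "N replacement steps" at constant size.
#'
#' Offspring inherit the midparent ancestry plus clipped Gaussian noise of
#' sd `offspring_noise_sd` (a stand-in for recombination variance).
#'
#' @param N0 Initial population size (default 1000).
#' @param mean_ai0 Initial mean AI ancestry proportion (default 0.42).
#' @param init_concentration Beta concentration of the initial ancestry
#'   distribution (default 20, i.e. sd about 0.11 at mean 0.42; `Inf` makes
#'   every founder exactly `mean_ai0`).
#' @param generations Number of generations to simulate; may be fractional
#'   (default 2).
#' @param growth_rate Per-generation exponential growth rate (default 0).
#' @param AM Assortative-mating strength in \[0,1\].
#' @param FAI Fecundity-difference strength, nonnegative.
#' @param M Migrant probability in \[0,1\].
#' @param mAI Migrant mean AI ancestry in \[0,1\].
#' @param migrant_concentration Beta concentration of migrant ancestry
#'   (`Inf` = point mass).
#' @param offspring_noise_sd Sd of the clipped Gaussian offspring noise.
#' @param fecundity_rule `"beta-top"` (default) draws the rank-from-top
#'   quantile from Beta(1, 1 + FAI); `"beta-reciprocal"` draws the
#'   ascending-rank quantile from Beta(1, 1/(1 + FAI)). Both are uniform at
#'   `FAI = 0` and have mean selection quantile (1 + FAI)/(2 + FAI) under
#'   the default rule.
#' @param record_every Record mean/variance every this many steps (default
#'   `max(1, floor(N0/20))`).
#' @param seed Optional default seed used by [moran_run()].
#' @return A `moran_params` list.
#' @seealso [moran_run()], [moran_sweep()]
#' @export
#' @examples
#' p <- moran_params(N0 = 200, AM = 0.75, FAI = 0.8, seed = 1)
moran_params <- function(N0 = 1000, mean_ai0 = 0.42, init_concentration = 20,
                         generations = 2, growth_rate = 0,
                         AM = 0, FAI = 0, M = 0, mAI = 0.5,
                         migrant_concentration = 10,
                         offspring_noise_sd = 0.02,
                         fecundity_rule = c("beta-top", "beta-reciprocal"),
                         record_every = NULL, seed = NULL) {
  fecundity_rule <- match.arg(fecundity_rule)
  if (N0 < 2) config_error("N0 must be at least 2")
  if (mean_ai0 <= 0 || mean_ai0 >= 1) config_error("mean_ai0 must be in (0,1)")
  if (init_concentration <= 0) config_error("init_concentration must be positive")
  if (generations <= 0) config_error("generations must be positive")
  if (AM < 0 || AM > 1) config_error("AM must be in [0,1]")
  if (FAI < 0) config_error("FAI must be nonnegative")
  if (M < 0 || M > 1) config_error("M must be in [0,1]")
  if (mAI < 0 || mAI > 1) config_error("mAI must be in [0,1]")
  if (migrant_concentration <= 0) config_error("migrant_concentration must be positive")
  if (offspring_noise_sd < 0) config_error("offspring_noise_sd must be nonnegative")
  p <- list(
    N0 = as.integer(N0), mean_ai0 = mean_ai0,
    init_concentration = init_concentration, generations = generations,
    growth_rate = growth_rate, AM = AM, FAI = FAI, M = M, mAI = mAI,
    migrant_concentration = migrant_concentration,
    offspring_noise_sd = offspring_noise_sd,
    fecundity_rule = fecundity_rule,
    record_every = record_every %||% max(1L, floor(N0 / 20)),
    seed = seed
  )
  class(p) <- "moran_params"
  p
}

#' Initialize a Moran population
#'
#' Founders' ancestry proportions are drawn from a Beta distribution with
#' the configured mean and concentration, then kept sorted (the simulator's
#' internal order).
#'
#' @param N0 Population size (>= 2).
#' @param mean_ai0 Mean initial AI ancestry, in (0,1).
#' @param concentration Beta concentration; `Inf` puts every founder at
#'   exactly `mean_ai0`.
#' @param seed Optional seed.
#' @return A `population_state` list with elements `ai` (sorted ancestry
#'   proportions), `birth_step`, `migrant`, `step` and `parent_log`.
#' @export
#' @examples
#' st <- init_population(100, 0.42, seed = 1)
#' mean(st$ai)
init_population <- function(N0, mean_ai0, concentration = 20, seed = NULL) {
  if (N0 < 2) config_error("N0 must be at least 2")
  if (mean_ai0 <= 0 || mean_ai0 >= 1) config_error("mean_ai0 must be in (0,1)")
  if (!is.null(seed)) set.seed(seed)
  ai <- sort(rbeta_mc(N0, mean_ai0, concentration))
  state <- list(
    ai = ai,
    birth_step = integer(N0),
    migrant = logical(N0),
    step = 0L,
    parent_log = matrix(numeric(0), ncol = 4,
                        dimnames = list(NULL, c("parent1_ai", "parent2_ai",
                                                "offspring_ai", "step")))
  )
  class(state) <- "population_state"
  state
}

#' Draw the fecundity rank quantile of the reproducing parent
#'
#' The first parent of a replacement event is the individual sitting at
#' ancestry-rank quantile `q` of the population (q near 1 = high-AI). Under
#' the default `"beta-top"` rule the rank-from-top quantile is
#' Beta(1, 1 + FAI) distributed, so `q = 1 - Beta(1, 1 + FAI)`, which is
#' equivalently Beta(1 + FAI, 1). `FAI = 0` gives a uniform quantile (no
#' fecundity differences); the mean selection quantile
#' `(1 + FAI)/(2 + FAI)` increases monotonically in `FAI`.
#'
#' @param FAI Fecundity-difference strength, nonnegative.
#' @param rule `"beta-top"` (default) or `"beta-reciprocal"`
#'   (Beta(1, 1/(1 + FAI)) on the ascending quantile).
#' @param n Number of draws.
#' @return Quantile(s) in \[0,1\]; values near 1 select high-AI parents.
#' @export
#' @examples
#' set.seed(1)
#' mean(fecundity_quantile(1, n = 1e4)) # about 2/3
fecundity_quantile <- function(FAI, rule = c("beta-top", "beta-reciprocal"),
                               n = 1) {
  rule <- match.arg(rule)
  if (FAI < 0) config_error("FAI must be nonnegative")
  if (rule == "beta-top") {
    stats::rbeta(n, 1 + FAI, 1)
  } else {
    stats::rbeta(n, 1, 1 / (1 + FAI))
  }
}

#' Choose the two parents of a replacement event
#'
#' Parent 1 is the individual at the fecundity rank quantile (see
#' [fecundity_quantile()]). With probability `AM`, parent 2 is parent 1's
#' nearest neighbour in ancestry proportion (ties broken uniformly, self
#' excluded); otherwise parent 2 is uniform over the remaining individuals.
#'
#' @param state A `population_state` (ancestry kept sorted).
#' @param AM Assortative-mating strength in \[0,1\].
#' @param FAI Fecundity-difference strength.
#' @param rule Fecundity rule, see [fecundity_quantile()].
#' @return Integer vector `c(parent1, parent2)` of indices into `state$ai`.
#' @export
choose_parents <- function(state, AM, FAI = 0,
                           rule = c("beta-top", "beta-reciprocal")) {
  rule <- match.arg(rule)
  N <- length(state$ai)
  if (N < 2) config_error("population size must be at least 2")
  .choose_parents_sorted(state$ai, AM, FAI, rule)
}

# internal kernel on the sorted ancestry vector
.choose_parents_sorted <- function(ai, AM, FAI, rule) {
  N <- length(ai)
  q <- fecundity_quantile(FAI, rule)
  i1 <- min(N, floor(q * N) + 1L)
  if (AM > 0 && stats::runif(1) < AM) {
    if (i1 == 1L) {
      i2 <- 2L
    } else if (i1 == N) {
      i2 <- N - 1L
    } else {
      dl <- ai[i1] - ai[i1 - 1L]
      dr <- ai[i1 + 1L] - ai[i1]
      i2 <- if (dl < dr) i1 - 1L
            else if (dr < dl) i1 + 1L
            else i1 + sample(c(-1L, 1L), 1L)
    }
  } else {
    i2 <- sample.int(N - 1L, 1L)
    if (i2 >= i1) i2 <- i2 + 1L
  }
  c(i1, i2)
}

#' Offspring ancestry from two parents
#'
#' Midparent value plus optional Gaussian noise, clipped to \[0,1\]. With
#' `noise_sd = 0` the offspring is exactly the midparent.
#'
#' @param parent1_ai,parent2_ai Parental ancestry proportions in \[0,1\].
#' @param noise_sd Nonnegative noise sd.
#' @return Offspring ancestry proportion in \[0,1\].
#' @export
#' @examples
#' make_offspring(0.2, 0.6, 0)
make_offspring <- function(parent1_ai, parent2_ai, noise_sd = 0) {
  mid <- (parent1_ai + parent2_ai) / 2
  if (noise_sd > 0) mid <- mid + stats::rnorm(length(mid), 0, noise_sd)
  clip(mid)
}

#' Draw a migrant's ancestry proportion
#'
#' Beta distributed with mean `mAI` and the given concentration;
#' `concentration = Inf` is a point mass at `mAI`.
#'
#' @param mAI Mean migrant AI ancestry in \[0,1\].
#' @param concentration Positive Beta concentration (may be `Inf`).
#' @param n Number of draws.
#' @return Ancestry proportion(s) in \[0,1\].
#' @export
migrant_ancestry <- function(mAI, concentration = 10, n = 1) {
  if (mAI < 0 || mAI > 1) config_error("mAI must be in [0,1]")
  if (concentration <= 0) config_error("concentration must be positive")
  rbeta_mc(n, mAI, concentration)
}

#' Advance a Moran population by one event
#'
#' One replacement event: with probability `M` the incoming individual is a
#' migrant, otherwise an offspring of two chosen parents (logged in
#' `parent_log`); a uniformly chosen resident dies. With `insert = TRUE`
#' the event is a scheduled growth insertion: a birth without a death.
#'
#' @param state A `population_state`.
#' @param params A [moran_params()] object.
#' @param insert Logical; birth-without-death growth event.
#' @return The updated `population_state`.
#' @export
moran_step <- function(state, params, insert = FALSE) {
  stopifnot(inherits(state, "population_state"), inherits(params, "moran_params"))
  ai <- state$ai
  N <- length(ai)
  pair <- NULL
  migrant_in <- FALSE
  if (params$M > 0 && stats::runif(1) < params$M) {
    newv <- migrant_ancestry(params$mAI, params$migrant_concentration)
    migrant_in <- TRUE
  } else {
    idx <- .choose_parents_sorted(ai, params$AM, params$FAI, params$fecundity_rule)
    pair <- ai[idx]
    newv <- make_offspring(pair[1], pair[2], params$offspring_noise_sd)
  }
  step <- state$step + 1L
  birth_step <- state$birth_step
  migr <- state$migrant
  if (!insert) {
    idie <- sample.int(N, 1L)
    ai <- ai[-idie]
    birth_step <- birth_step[-idie]
    migr <- migr[-idie]
  }
  pos <- findInterval(newv, ai)
  ai <- append(ai, newv, after = pos)
  birth_step <- append(birth_step, step, after = pos)
  migr <- append(migr, migrant_in, after = pos)
  state$ai <- ai
  state$birth_step <- birth_step
  state$migrant <- migr
  state$step <- step
  if (!is.null(pair)) {
    state$parent_log <- rbind(state$parent_log,
                              c(pair[1], pair[2], newv, step))
  }
  state
}

#' Run the Moran simulator
#'
#' Executes `generations * N` replacement steps (N per generation,
#' re-evaluated at each generation boundary under growth), recording the
#' population mean and variance of ancestry along the way and logging every
#' non-migrant mating's parental ancestry pair.
#'
#' @param params A [moran_params()] object.
#' @param seed Seed for the run (falls back to `params$seed`).
#' @return A `moran_trajectory` list: `record` (data.frame of `step`,
#'   `mean`, `var`), `parent_pairs` (two-column matrix), `parent_r`
#'   (Pearson correlation of parental pairs), `initial_mean`, `final_mean`,
#'   `pct_change` (relative change of the mean in percent), `final_size`
#'   and `params`.
#' @export
#' @examples
#' tr <- moran_run(moran_params(N0 = 100, generations = 1), seed = 1)
#' tr$pct_change
moran_run <- function(params, seed = NULL) {
  stopifnot(inherits(params, "moran_params"))
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)

  AM <- params$AM; FAI <- params$FAI; M <- params$M
  mAI <- params$mAI; mconc <- params$migrant_concentration
  noise <- params$offspring_noise_sd
  frule <- params$fecundity_rule
  rec_every <- params$record_every

  ai <- sort(rbeta_mc(params$N0, params$mean_ai0, params$init_concentration))
  initial_mean <- mean(ai)

  n_steps_max <- ceiling(params$generations * params$N0 *
                           exp(max(0, params$growth_rate) * params$generations)) + 16L
  p1l <- numeric(n_steps_max); p2l <- numeric(n_steps_max); npair <- 0L
  rec_step <- integer(0); rec_mean <- numeric(0); rec_var <- numeric(0)

  record <- function(step) {
    rec_step[[length(rec_step) + 1L]] <<- step
    rec_mean[[length(rec_mean) + 1L]] <<- mean(ai)
    rec_var[[length(rec_var) + 1L]] <<- stats::var(ai)
  }
  record(0L)

  gens_left <- params$generations
  gens_done <- 0
  global_step <- 0L
  while (gens_left > 1e-12) {
    frac <- min(1, gens_left)
    N_start <- length(ai)
    steps_g <- max(1L, as.integer(round(frac * N_start)))
    N_target <- as.integer(round(params$N0 *
                                   exp(params$growth_rate * (gens_done + frac))))
    n_insert <- max(0L, N_target - N_start)
    insert_at <- if (n_insert > 0) {
      unique(as.integer(round(seq(1, steps_g, length.out = n_insert))))
    } else integer(0)
    # if rounding collapsed scheduled slots, top up at the end of the generation
    extra <- n_insert - length(insert_at)

    ins_ptr <- 1L
    for (s in seq_len(steps_g)) {
      is_insert <- ins_ptr <= length(insert_at) && insert_at[ins_ptr] == s
      if (is_insert) ins_ptr <- ins_ptr + 1L
      N <- length(ai)
      if (M > 0 && stats::runif(1) < M) {
        newv <- if (is.finite(mconc)) rbeta_mc(1, mAI, mconc) else mAI
      } else {
        idx <- .choose_parents_sorted(ai, AM, FAI, frule)
        npair <- npair + 1L
        p1l[npair] <- ai[idx[1]]; p2l[npair] <- ai[idx[2]]
        newv <- (ai[idx[1]] + ai[idx[2]]) / 2
        if (noise > 0) newv <- min(1, max(0, newv + stats::rnorm(1, 0, noise)))
      }
      if (!is_insert) ai <- ai[-sample.int(N, 1L)]
      ai <- append(ai, newv, after = findInterval(newv, ai))
      global_step <- global_step + 1L
      if (global_step %% rec_every == 0L) record(global_step)
    }
    if (extra > 0L) {
      for (k in seq_len(extra)) {
        idx <- .choose_parents_sorted(ai, AM, FAI, frule)
        newv <- make_offspring(ai[idx[1]], ai[idx[2]], noise)
        ai <- append(ai, newv, after = findInterval(newv, ai))
      }
    }
    gens_done <- gens_done + frac
    gens_left <- gens_left - frac
  }
  if (rec_step[length(rec_step)] != global_step) record(global_step)

  pairs <- cbind(parent1_ai = p1l[seq_len(npair)],
                 parent2_ai = p2l[seq_len(npair)])
  parent_r <- if (npair >= 3 && stats::sd(pairs[, 1]) > 0 && stats::sd(pairs[, 2]) > 0) {
    stats::cor(pairs[, 1], pairs[, 2])
  } else NA_real_
  final_mean <- mean(ai)
  out <- list(
    record = data.frame(step = rec_step, mean = rec_mean, var = rec_var),
    parent_pairs = pairs,
    parent_r = parent_r,
    initial_mean = initial_mean,
    final_mean = final_mean,
    pct_change = 100 * (final_mean - initial_mean) / initial_mean,
    final_size = length(ai),
    params = params
  )
  class(out) <- "moran_trajectory"
  out
}

#' @export
print.moran_trajectory <- function(x, ...) {
  cat("Moran trajectory:", nrow(x$record), "records,",
      nrow(x$parent_pairs), "matings\n")
  cat(sprintf("  mean ancestry %.4f -> %.4f (%+.2f%%), parental r = %.3f\n",
              x$initial_mean, x$final_mean, x$pct_change, x$parent_r))
  invisible(x)
}

#' Sweep the Moran simulator over a parameter grid
#'
#' Runs `replicates` seeded replicates at every row of `grid` (columns name
#' [moran_params()] arguments; unspecified parameters take their defaults
#' or the values in `base`). Seeds fan out deterministically from the
#' run-level seed, so the table is bit-identical across calls.
#'
#' @param grid A data.frame; each row is one parameter combination.
#' @param replicates Replicates per grid row.
#' @param seed Run-level seed.
#' @param base Optional [moran_params()] supplying non-swept values.
#' @return A data.frame with the grid columns plus `replicate`,
#'   `pct_change`, `parent_r`, `var_initial`, `var_final`; the per-row
#'   means are available through `attr(, "summary")`.
#' @export
moran_sweep <- function(grid, replicates = 10, seed = 1, base = NULL) {
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    config_error("parameter grid must be a non-empty data.frame")
  }
  base_args <- if (is.null(base)) list() else unclass(base)[
    setdiff(names(unclass(base)), c("record_every", "seed"))]
  rows <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    args <- base_args
    for (nm in names(grid)) args[[nm]] <- grid[[nm]][g]
    p <- do.call(moran_params, args)
    for (r in seq_len(replicates)) {
      tr <- moran_run(p, seed = child_seed(seed, "sweep", g, r))
      k <- k + 1L
      rows[[k]] <- cbind(grid[g, , drop = FALSE],
                         data.frame(replicate = r,
                                    pct_change = tr$pct_change,
                                    parent_r = tr$parent_r,
                                    var_initial = tr$record$var[1],
                                    var_final = tr$record$var[nrow(tr$record)]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  agg <- stats::aggregate(out[c("pct_change", "parent_r", "var_final")],
                          by = out[names(grid)], FUN = mean)
  attr(out, "summary") <- agg
  out
}
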