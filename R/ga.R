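#' Flatten model weights to a chromosome and back
#'
#' The genetic search works on a flat real vector ("chromosome") holding
#' every weight of the network in a fixed documented order (the order of the
#' parameter tensors in the model, column-major within each tensor).
#' `unflatten_weights()` is the exact inverse of `flatten_weights()`.
#'
#' @param model A `sers_cnn` model.
#' @param chrom Numeric vector of length `count_params(model$config)`.
#' @return `flatten_weights()`: a numeric vector; `unflatten_weights()`: a
#'   model with the chromosome's weights loaded.
#' @export
flatten_weights <- function(model) {
  unlist(model$params, use.names = FALSE)
}

#' @rdname flatten_weights
#' @export
unflatten_weights <- function(chrom, model) {
  if (length(chrom) != length(unlist(model$params, use.names = FALSE))) {
    stop_shape("chromosome length must equal the model's parameter count")
  }
  if (!all(is.finite(chrom))) stop_value("chromosome entries must be finite")
  model$params <- relist_params(chrom, model$params)
  model
}

#' Genetic-search configuration
#'
#' Settings of the adaptive genetic algorithm that searches the network's
#' initial weights. Crossover and mutation probabilities adapt per
#' individual between their configured bounds according to how the
#' individual's fitness compares with the population average and best, and
#' anneal towards the lower bound as generations progress (see
#' [adaptive_rates()]). The optional catastrophe operator reinitialises the
#' worst fraction of a stagnating population; it is off by default.
#'
#' @param pop_size Population size (>= 2).
#' @param generations Maximum generations `G` (>= 0).
#' @param pc_min,pc_max Crossover probability bounds in `(0, 1]`.
#' @param pm_min,pm_max Mutation probability bounds in `(0, 1]`.
#' @param sigmoid_a Steepness `A` of the adaptive sigmoid (> 0).
#' @param elitism Number of best individuals copied unchanged (>= 1).
#' @param mutation_scale Standard deviation of the Gaussian gene
#'   perturbation; `NULL` uses 0.1 of the spread of the initial population.
#' @param catastrophe Enable the stagnation-triggered restart.
#' @param stagnation_window Generations without improvement before a
#'   catastrophe fires.
#' @param refresh_fraction Fraction of worst individuals reinitialised.
#' @param seed Seed for all GA randomness.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 30, generations = 50,
                      pc_min = 0.4, pc_max = 0.9,
                      pm_min = 0.01, pm_max = 0.1,
                      sigmoid_a = 1, elitism = 1,
                      mutation_scale = NULL,
                      catastrophe = FALSE, stagnation_window = 10,
                      refresh_fraction = 0.5, seed = 1L) {
  cfg <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              pc_min = pc_min, pc_max = pc_max,
              pm_min = pm_min, pm_max = pm_max,
              sigmoid_a = sigmoid_a, elitism = as.integer(elitism),
              mutation_scale = mutation_scale,
              catastrophe = isTRUE(catastrophe),
              stagnation_window = as.integer(stagnation_window),
              refresh_fraction = refresh_fraction,
              seed = as.integer(seed))
  if (cfg$pop_size < 2) stop_config("pop_size must be >= 2")
  if (cfg$generations < 0) stop_config("generations must be >= 0")
  if (!(cfg$pc_min < cfg$pc_max) || cfg$pc_min <= 0 || cfg$pc_max > 1) {
    stop_config("need 0 < pc_min < pc_max <= 1")
  }
  if (!(cfg$pm_min < cfg$pm_max) || cfg$pm_min <= 0 || cfg$pm_max > 1) {
    stop_config("need 0 < pm_min < pm_max <= 1")
  }
  if (cfg$sigmoid_a <= 0) stop_config("sigmoid_a must be > 0")
  if (cfg$elitism < 1 || cfg$elitism >= cfg$pop_size) {
    stop_config("need 1 <= elitism < pop_size")
  }
  if (cfg$refresh_fraction <= 0 || cfg$refresh_fraction >= 1) {
    stop_config("refresh_fraction must be in (0, 1)")
  }
  if (cfg$stagnation_window < 1) stop_config("stagnation_window must be >= 1")
  class(cfg) <- "ga_config"
  cfg
}

#' Adaptive crossover and mutation probabilities
#'
#' Fitness here is an error to be minimised, while the adaptive schedule is
#' written for a maximised fitness, so the rule is applied on the quality
#' scale `q = -error`. For an individual at least as good as the population
#' average (and a non-degenerate population),
#' `P = P_min + (P_max - P_min) (1 - i/G) / (1 + exp(A * 2 (q - q_avg) / (q_best - q_avg)))`;
#' below-average individuals (and the degenerate case `q_best == q_avg`,
#' including equality with the average) get `P_max`, so weak individuals
#' explore at the maximum rate. The `(1 - i/G)` factor anneals the adapted
#' rate towards `P_min` by the final generation. Probabilities are always
#' clamped to `[P_min, P_max]`.
#'
#' @param f Individual's error (lower is better).
#' @param f_avg Population mean error.
#' @param f_best Population best (lowest) error.
#' @param i Current generation, `0 <= i <= G`.
#' @param G Maximum generations (>= 1).
#' @param cfg A [ga_config()] supplying the bounds and `A`.
#' @return A list with elements `pc` and `pm`.
#' @examples
#' cfg <- ga_config()
#' adaptive_rates(f = 0.1, f_avg = 0.5, f_best = 0.1, i = 0, G = 50, cfg)
#' @export
adaptive_rates <- function(f, f_avg, f_best, i, G, cfg) {
  list(
    pc = adaptive_rate(f, f_avg, f_best, i, G, cfg$pc_min, cfg$pc_max,
                       cfg$sigmoid_a),
    pm = adaptive_rate(f, f_avg, f_best, i, G, cfg$pm_min, cfg$pm_max,
                       cfg$sigmoid_a)
  )
}

adaptive_rate <- function(f, f_avg, f_best, i, G, p_min, p_max, a) {
  q <- -f
  q_avg <- -f_avg
  q_best <- -f_best
  if (!is.finite(q) || !is.finite(q_avg) || !is.finite(q_best) ||
      q <= q_avg || q_best <= q_avg) {
    # at or below average quality (and in degenerate populations) explore at
    # the maximum rate; equality deliberately resolves to this branch
    return(p_max)
  }
  frac <- max(0, 1 - i / G)
  p <- p_min + (p_max - p_min) * frac /
    (1 + exp(a * 2 * (q - q_avg) / (q_best - q_avg)))
  min(max(p, p_min), p_max)
}

#' Chromosome fitness: training-set RMSE of a forward pass
#'
#' Loads the chromosome into the model and computes the root mean squared
#' error of a pure forward pass on the training data -- no gradient steps are
#' taken inside fitness evaluation. Chromosomes producing non-finite
#' predictions get `Inf`, so they can never be selected as elites.
#'
#' @param chrom Flat weight vector.
#' @param model A `sers_cnn` template of matching size.
#' @param x Scaled intensity matrix (samples x channels) or `spectra_tbl`.
#' @param y Scaled targets.
#' @return A single error value (lower is better).
#' @export
chromosome_fitness <- function(chrom, model, x, y) {
  m <- unflatten_weights(chrom, model)
  yhat <- tryCatch(predict(m, x), error = function(e) NULL)
  if (is.null(yhat) || any(!is.finite(yhat))) return(Inf)
  metric_rmse(y, yhat)
}

#' GA variation operators
#'
#' `tournament_pairs()` draws parent index pairs by size-2 tournaments on
#' error (lower wins; on a tie the first-drawn candidate is kept).
#' `crossover_blend()` performs arithmetic blend crossover with probability
#' `pc`: children `alpha * a + (1 - alpha) * b` and its complement, with an
#' independent mixing coefficient `alpha ~ U(0, 1)` per gene (so
#' `child1 + child2 == a + b` exactly, gene by gene); otherwise the children
#' are copies. Per-gene mixing explores the whole box spanned by the
#' parents rather than the line segment between them, which mixes
#' substantially better in high dimension. `mutate_chromosome()` perturbs
#' each gene independently with probability `pm` by `N(0, scale^2)` noise.
#'
#' @param fitnesses Numeric vector of errors, one per individual.
#' @param n_pairs Number of parent pairs to draw.
#' @param a,b,chrom Chromosomes (equal-length numeric vectors).
#' @param pc,pm Crossover / per-gene mutation probabilities.
#' @param scale Mutation standard deviation (> 0).
#' @return `tournament_pairs()`: integer matrix `[n_pairs x 2]`;
#'   `crossover_blend()`: list of two children; `mutate_chromosome()`: a
#'   chromosome.
#' @export
tournament_pairs <- function(fitnesses, n_pairs) {
  n <- length(fitnesses)
  pick_one <- function() {
    cand <- sample.int(n, 2, replace = TRUE)
    better <- if (fitnesses[cand[2]] < fitnesses[cand[1]]) cand[2] else cand[1]
    better
  }
  matrix(vapply(seq_len(2 * n_pairs), function(i) pick_one(), integer(1)),
         ncol = 2, byrow = TRUE)
}

#' @rdname tournament_pairs
#' @export
crossover_blend <- function(a, b, pc) {
  if (length(a) != length(b)) stop_shape("parents must have equal length")
  if (stats::runif(1) >= pc) return(list(a, b))
  alpha <- stats::runif(length(a))
  list(alpha * a + (1 - alpha) * b, (1 - alpha) * a + alpha * b)
}

#' @rdname tournament_pairs
#' @export
mutate_chromosome <- function(chrom, pm, scale) {
  if (scale <= 0) stop_value("mutation scale must be > 0")
  hit <- stats::runif(length(chrom)) < pm
  if (any(hit)) {
    chrom[hit] <- chrom[hit] + stats::rnorm(sum(hit), sd = scale)
  }
  chrom
}

#' Generic adaptive genetic search
#'
#' Minimises `fitness_fn` over real vectors. This is the engine behind
#' [run_ga()], exposed separately so it can be exercised on analytic test
#' surrogates (e.g. the sphere function). Per generation it breeds a full
#' population of children from tournament-selected parents (blend
#' crossover and Gaussian mutation, with rates adapted per parent pair via
#' [adaptive_rates()]), then applies truncation survivor selection: parents
#' and children compete and the best `pop_size` survive. No good solution
#' is ever lost -- the configured number of elites is, a fortiori, carried
#' unchanged -- so the best-fitness trajectory is non-increasing. The
#' optional catastrophe restart reinitialises the worst individuals after
#' prolonged stagnation. Everything is reproducible from `cfg$seed`.
#'
#' @param fitness_fn Function mapping a numeric vector to an error scalar.
#' @param init_fn Function `(k)` returning the k-th initial individual (also
#'   used to draw catastrophe replacements).
#' @param cfg A [ga_config()].
#' @return A `ga_result` list: `best` (chromosome), `best_fitness`,
#'   `trajectory` (tibble of `generation`, `best`), `population` (matrix),
#'   `fitness` (final population errors).
#' @export
ga_search <- function(fitness_fn, init_fn, cfg) {
  with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$pop_size), init_fn)
    eval_pop <- function(p) purrr::map_dbl(p, fitness_fn)
    fit <- eval_pop(pop)
    scale <- cfg$mutation_scale
    if (is.null(scale)) {
      spread <- stats::sd(unlist(pop))
      scale <- if (is.finite(spread) && spread > 0) 0.1 * spread else 0.01
    }
    traj <- numeric(cfg$generations)
    stagnant <- 0L
    prev_best <- min(fit)
    if (cfg$generations > 0) {
      for (gen in seq_len(cfg$generations)) {
        f_avg <- mean(fit[is.finite(fit)])
        if (!is.finite(f_avg)) f_avg <- min(fit)
        f_best <- min(fit)
        sc_gen <- scale
        pairs <- tournament_pairs(fit, ceiling(cfg$pop_size / 2))
        children <- vector("list", 0)
        for (r in seq_len(nrow(pairs))) {
          i1 <- pairs[r, 1]; i2 <- pairs[r, 2]
          fitter <- min(fit[i1], fit[i2])
          rates <- adaptive_rates(fitter, f_avg, f_best, gen - 1,
                                  cfg$generations, cfg)
          kids <- crossover_blend(pop[[i1]], pop[[i2]], rates$pc)
          kids <- lapply(kids, mutate_chromosome, pm = rates$pm,
                         scale = sc_gen)
          children <- c(children, kids)
        }
        # (mu + lambda) truncation survival: parents and children compete and
        # the best pop_size survive, so no good solution is ever lost (the
        # elites are, a fortiori, copied unchanged)
        children <- children[seq_len(cfg$pop_size)]
        child_fit <- eval_pop(children)
        pool <- c(pop, children)
        pool_fit <- c(fit, child_fit)
        keep <- order(pool_fit)[seq_len(cfg$pop_size)]
        pop <- pool[keep]
        fit <- pool_fit[keep]
        best_now <- min(fit)
        if (best_now < prev_best - .Machine$double.eps) {
          stagnant <- 0L
        } else {
          stagnant <- stagnant + 1L
        }
        prev_best <- min(prev_best, best_now)
        if (cfg$catastrophe && stagnant >= cfg$stagnation_window) {
          n_refresh <- max(1L, floor(cfg$refresh_fraction * cfg$pop_size))
          worst <- order(fit, decreasing = TRUE)[seq_len(n_refresh)]
          worst <- setdiff(worst, order(fit)[seq_len(cfg$elitism)])
          for (j in worst) pop[[j]] <- init_fn(j)
          fit <- eval_pop(pop)
          stagnant <- 0L
        }
        traj[gen] <- prev_best
      }
    }
    best_idx <- which.min(fit)
    structure(
      list(best = pop[[best_idx]], best_fitness = fit[best_idx],
           trajectory = tibble::tibble(
             generation = seq_len(cfg$generations), best = traj
           ),
           population = do.call(rbind, pop), fitness = fit),
      class = "ga_result"
    )
  })
}

#' Search the network's initial weights with the adaptive GA
#'
#' Builds `pop_size` independently seeded weight initialisations of the
#' model, evolves them with [ga_search()] under the training-set RMSE
#' fitness of [chromosome_fitness()], and returns the best chromosome --
#' intended to be passed to [train_network()] as `init` so gradient descent
#' starts from the fittest weights found.
#'
#' @param model A `sers_cnn` template from [build_model()].
#' @param x Scaled intensity matrix (samples x channels) or `spectra_tbl`.
#' @param y Scaled targets.
#' @param cfg A [ga_config()].
#' @return A `ga_result` (see [ga_search()]).
#' @export
run_ga <- function(model, x, y, cfg = ga_config()) {
  xm <- if (is.matrix(x)) x else spectra_matrix(as_spectra(x))
  if (length(y) != nrow(xm)) stop_shape("one target per sample required")
  # one shared workspace keeps the ~1.5k fitness forward passes allocation-free
  xa <- spectra_to_input(xm)
  wsp <- new_workspace(model$config, nrow(xm))
  template <- model$params
  fitness_fn <- function(chrom) {
    if (any(!is.finite(chrom))) return(Inf)
    params <- relist_params(chrom, template)
    yhat <- model_forward(params, model$config, xa, ws = wsp)$yhat
    if (any(!is.finite(yhat))) return(Inf)
    metric_rmse(y, yhat)
  }
  init_fn <- function(k) {
    flatten_weights(build_model(model$config,
                                seed = derive_seed(cfg$seed, 100 + k)))
  }
  ga_search(fitness_fn, init_fn, cfg)
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result>\n")
  cat("  dimensions:", ncol(x$population), "\n")
  cat("  generations:", nrow(x$trajectory), "\n")
  cat("  best fitness:", format(x$best_fitness), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.ga_result <- function(x, ...) x$trajectory
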