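#' Colony configuration for the (mutual-learning) artificial bee colony
#'
#' @param num_bees number of food sources (>= 2; the mutual update needs a
#'   neighbor distinct from the current source). Onlooker bees equal
#'   employed bees, the conventional equal split.
#' @param max_cycles number of employed/onlooker/scout cycles.
#' @param limit failed-improvement count after which a source is abandoned
#'   and its bee scouts a fresh random position.
#' @param F mutual-learning coefficient (> 0); the per-dimension step
#'   coefficient is drawn uniformly from `[0, F]`. Large `F` trades
#'   exploitation accuracy for disruption, so the default is 1.
#' @param seed integer seed.
#' @return A `colony_config` object.
#' @export
colony_config <- function(num_bees = 20, max_cycles = 200, limit = 20,
                          F = 1, seed = 1) {
  structure(
    list(
      num_bees = check_number(num_bees, "num_bees", 2, integer = TRUE),
      max_cycles = check_number(max_cycles, "max_cycles", 1, integer = TRUE),
      limit = check_number(limit, "limit", 1, integer = TRUE),
      F = check_number(F, "F", 0, open_lo = TRUE),
      seed = check_number(seed, "seed", integer = TRUE)
    ),
    class = "colony_config"
  )
}

new_food_source <- function(position, fitness) {
  list(position = position, fitness = fitness, trial = 0L)
}

eval_fitness <- function(fitness_fn, genome) {
  f <- tryCatch(fitness_fn(genome), error = function(e) {
    stop(sprintf("fitness_fn failed on genome [%s]: %s",
                 paste(signif(genome, 6), collapse = ", "),
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
    abort_field("fitness_fn", "must return a single finite number")
  }
  f
}

#' Initialize the colony
#'
#' Places `num_bees` food sources uniformly in the unit box (the random-key
#' genome domain) and evaluates each once.
#'
#' @param space a [search_space()] (fixes the genome dimension).
#' @param config a [colony_config()].
#' @param fitness_fn function mapping a genome to a finite scalar fitness
#'   (maximization convention).
#' @return List of food sources `list(position, fitness, trial)`.
#' @export
initialize_colony <- function(space, config, fitness_fn) {
  D <- space_dimension(space)
  withr::local_seed(config$seed)
  lapply(seq_len(config$num_bees), function(i) {
    pos <- stats::runif(D) # x_min + rand(0,1) * (x_max - x_min) on [0,1]
    new_food_source(pos, eval_fitness(fitness_fn, pos))
  })
}

#' Mutual-learning candidate position
#'
#' The mutual-learning update replaces the blind perturbation of classic
#' ABC with a fitness-guided move between a current/neighbor pair: the
#' candidate starts from the worse of the two positions and moves toward
#' the better one by a per-dimension coefficient `phi ~ U(0, F)`; the
#' result is clipped to the unit box. For `F <= 1` every coordinate lies in
#' the interval spanned by the pair.
#'
#' @param current,neighbor food sources (`list(position, fitness, trial)`).
#' @param F mutual-learning coefficient > 0.
#' @param seed optional seed; `NULL` uses the ambient RNG stream.
#' @return Candidate genome in `[0, 1]^D`.
#' @export
mutual_candidate <- function(current, neighbor, F = 1, seed = NULL) {
  if (identical(current, neighbor)) {
    abort_field("neighbor", "must be a food source distinct from current")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  mutual_step(current, neighbor, F)
}

# the Eq.-style update without the distinctness guard: converged colonies
# legitimately hold coincident positions, where the step is a no-op
mutual_step <- function(current, neighbor, F) {
  phi <- stats::runif(length(current$position), 0, F)
  v <- if (current$fitness < neighbor$fitness) {
    current$position + phi * (neighbor$position - current$position)
  } else {
    neighbor$position + phi * (current$position - neighbor$position)
  }
  pmin(pmax(v, 0), 1)
}

# single-dimension proposal used inside the optimizer: conventional ABC
# modifies one randomly chosen dimension per update; the mutual variant
# applies the fitness-guided rule to that coordinate, the classic variant
# the blind perturbation v_j = x_ij + phi (x_ij - x_kj), phi ~ U(-1, 1)
propose_candidate <- function(current, neighbor, F, variant) {
  v <- current$position
  j <- sample.int(length(v), 1L)
  if (variant == "mutual") {
    phi <- stats::runif(1L, 0, F)
    v[j] <- if (current$fitness < neighbor$fitness) {
      current$position[j] + phi * (neighbor$position[j] - current$position[j])
    } else {
      neighbor$position[j] + phi * (current$position[j] - neighbor$position[j])
    }
  } else {
    phi <- stats::runif(1L, -1, 1)
    v[j] <- current$position[j] + phi * (current$position[j] -
                                           neighbor$position[j])
  }
  v[j] <- min(max(v[j], 0), 1)
  v
}

# classic ABC fitness transform making values positive for the roulette
# wheel; monotone increasing in raw (maximized) fitness
abc_fit_transform <- function(f) ifelse(f >= 0, 1 + f, 1 / (1 - f))

#' Onlooker selection probabilities
#'
#' Fitness-proportional probabilities `p_i = fit_i / sum(fit)` over the
#' colony, after the positivity transform (`1 + f` for `f >= 0`,
#' `1 / (1 - f)` otherwise) applied to the raw maximized fitness.
#'
#' @param colony list of food sources.
#' @return Probability vector summing to 1.
#' @export
onlooker_probabilities <- function(colony) {
  f <- vapply(colony, `[[`, 1, "fitness")
  if (any(!is.finite(f))) abort_field("colony", "non-finite fitness")
  fit <- abc_fit_transform(f)
  if (any(fit <= 0)) abort_field("colony", "non-positive transformed fitness")
  fit / sum(fit)
}

greedy_update <- function(colony, i, candidate, fitness_fn) {
  f_new <- eval_fitness(fitness_fn, candidate)
  if (f_new > colony[[i]]$fitness) {
    colony[[i]] <- new_food_source(candidate, f_new)
  } else {
    colony[[i]]$trial <- colony[[i]]$trial + 1L
  }
  colony
}

#' Run the artificial bee colony optimizer
#'
#' Cycles of employed, onlooker and scout phases with greedy replacement:
#' a candidate replaces its source only on strict fitness improvement,
#' otherwise the source's trial counter grows; sources stuck for `limit`
#' trials are re-initialized uniformly (the scout move). Following the
#' conventional ABC update, each proposal modifies one randomly chosen
#' dimension: the `"mutual"` variant applies the fitness-guided pairwise
#' rule to that coordinate, `"classic"` the blind perturbation.
#'
#' @param space a [search_space()].
#' @param config a [colony_config()].
#' @param fitness_fn genome -> finite scalar, maximized.
#' @param variant `"mutual"` (default) or `"classic"`.
#' @return An `abc_fit`: `best` food source (best-ever), `history` tibble
#'   of per-cycle best/mean fitness (best is monotone non-decreasing), the
#'   decoded best configuration, and an evaluation count.
#' @examples
#' sp <- search_space(lapply(1:3, \(i) param_continuous(paste0("x", i), -1, 1)))
#' sphere <- function(g) -sum(unlist(decode_genome(g, sp))^2)
#' fit <- abc_optimize(sp, colony_config(num_bees = 10, max_cycles = 30), sphere)
#' fit$best$fitness
#' @export
abc_optimize <- function(space, config, fitness_fn,
                         variant = c("mutual", "classic")) {
  variant <- match.arg(variant)
  colony <- initialize_colony(space, config, fitness_fn)
  n_eval <- config$num_bees
  withr::local_seed(derive_seed(config$seed, 11))
  propose <- function(colony, i) {
    k <- sample(setdiff(seq_along(colony), i), 1L)
    propose_candidate(colony[[i]], colony[[k]], config$F, variant)
  }
  best <- colony[[which.max(vapply(colony, `[[`, 1, "fitness"))]]
  history <- vector("list", config$max_cycles)
  for (cycle in seq_len(config$max_cycles)) {
    for (i in seq_along(colony)) { # employed phase
      colony <- greedy_update(colony, i, propose(colony, i), fitness_fn)
      n_eval <- n_eval + 1L
    }
    p <- onlooker_probabilities(colony)
    for (b in seq_along(colony)) { # onlooker phase
      i <- sample.int(length(colony), 1L, prob = p)
      colony <- greedy_update(colony, i, propose(colony, i), fitness_fn)
      n_eval <- n_eval + 1L
    }
    for (i in seq_along(colony)) { # scout phase
      if (colony[[i]]$trial >= config$limit) {
        pos <- stats::runif(space_dimension(space))
        colony[[i]] <- new_food_source(pos, eval_fitness(fitness_fn, pos))
        n_eval <- n_eval + 1L
      }
    }
    fits <- vapply(colony, `[[`, 1, "fitness")
    if (max(fits) > best$fitness) best <- colony[[which.max(fits)]]
    history[[cycle]] <- tibble::tibble(
      cycle = cycle, best_fitness = best$fitness, mean_fitness = mean(fits)
    )
  }
  structure(
    list(best = best, history = dplyr::bind_rows(history),
         best_config = decode_genome(best$position, space),
         n_evaluations = n_eval, variant = variant,
         space = space, config = config),
    class = "abc_fit"
  )
}

#' @export
print.abc_fit <- function(x, ...) {
  cat(sprintf("<abc_fit> %s variant, %d bees x %d cycles (%d evaluations)\n",
              x$variant, x$config$num_bees, x$config$max_cycles,
              x$n_evaluations))
  cat(sprintf("  best fitness: %.6g\n", x$best$fitness))
  invisible(x)
}

#' Tune SS-GAN hyperparameters with ML-ABC
#'
#' Runs the colony over the published generator search space (noise size,
#' depth, activation, dropout, learning rate, reconstruction weight, ...)
#' with a short-budget training run per evaluation; the fitness is the
#' validation F-measure of the resulting discriminator.
#'
#' @param data feature tibble with `split` tags and masked labels.
#' @param space a [search_space()]; default [desk_generator_space()], a
#'   CPU-sized restriction of the published ranges.
#' @param config a [colony_config()] (small budgets recommended: each
#'   evaluation trains a model).
#' @param budget_epochs reduced epoch budget per fitness evaluation
#'   (overrides any `epochs` gene).
#' @param base_config template [training_config()] for fields the space
#'   does not tune.
#' @return An `abc_fit`, with `best_training_config` attached.
#' @export
tune_ssgan <- function(data, space = desk_generator_space(),
                       config = colony_config(num_bees = 6, max_cycles = 5,
                                              limit = 5),
                       budget_epochs = 5,
                       base_config = training_config()) {
  as_training_config <- function(genome) {
    cfg <- decode_genome(genome, space)
    tc <- base_config
    if (!is.null(cfg$batch_size)) tc$batch_size <- cfg$batch_size
    if (!is.null(cfg$learning_rate)) {
      tc$lr_g <- cfg$learning_rate; tc$lr_d <- cfg$learning_rate
    }
    if (!is.null(cfg$noise_size)) tc$noise_size <- cfg$noise_size
    spec <- mlp_spec(
      n_layers = cfg$n_layers %||% tc$g_spec$n_layers,
      hidden_width = tc$g_spec$hidden_width,
      activation = cfg$activation %||% tc$g_spec$activation,
      dropout_rate = cfg$dropout_rate %||% tc$g_spec$dropout_rate
    )
    tc$g_spec <- spec; tc$d_spec <- spec
    if (!is.null(cfg$lambda)) tc$weights$lambda_r <- cfg$lambda
    if (!is.null(cfg$lambda_consistency)) {
      tc$weights$lambda_consistency <- cfg$lambda_consistency
    }
    if (!is.null(cfg$lambda_pseudo)) {
      tc$weights$lambda_pseudo <- cfg$lambda_pseudo
    }
    tc$epochs <- budget_epochs
    tc$seed <- derive_seed(config$seed, 101) # fixed per evaluation
    tc
  }
  fitness_fn <- function(genome) {
    tc <- as_training_config(genome)
    fit <- tryCatch(train_ssgan(data, tc), error = function(e) NULL)
    if (is.null(fit)) return(0) # diverged configurations score worst
    fm <- dplyr::last(fit$history$val_f_measure)
    if (is.null(fm) || !is.finite(fm)) 0 else fm
  }
  out <- abc_optimize(space, config, fitness_fn, variant = "mutual")
  out$best_training_config <- as_training_config(out$best$position)
  out
}
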