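#' Random-key hyperparameter encodings
#'
#' A random-key genome is a real vector in `[0, 1]^D` that decodes into a
#' mixed continuous/integer/categorical configuration, so a box-constrained
#' metaheuristic can search the space without ever producing an invalid
#' configuration. Continuous and integer parameters take one gene
#' (`D_c = 1`); a categorical parameter with `K` options takes a sub-vector
#' of length `K` and decodes to the option at the argmax position.
#'
#' @param name parameter name.
#' @param lo,hi range bounds (`lo < hi`).
#' @return A `hyperparam_spec` object.
#' @name random_key
NULL

#' @rdname random_key
#' @export
param_continuous <- function(name, lo, hi) {
  if (!is.character(name) || !nzchar(name)) abort_field("name", "required")
  if (!(lo < hi)) abort_field(name, "requires lo < hi")
  structure(list(name = name, kind = "continuous", lo = lo, hi = hi,
                 D_c = 1L), class = "hyperparam_spec")
}

#' @rdname random_key
#' @export
param_integer <- function(name, lo, hi) {
  sp <- param_continuous(name, lo, hi)
  sp$kind <- "integer"
  sp
}

#' @rdname random_key
#' @param options character vector of at least two category labels.
#' @export
param_categorical <- function(name, options) {
  if (length(options) < 2L) abort_field(name, "needs >= 2 options")
  structure(list(name = name, kind = "categorical",
                 options = as.character(options),
                 D_c = length(options)), class = "hyperparam_spec")
}

#' Assemble a search space from parameter specs
#'
#' @param ... `hyperparam_spec` objects (or one list of them).
#' @return A `search_space` whose total dimension is the sum of the
#'   per-parameter sub-vector lengths.
#' @export
search_space <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "hyperparam_spec")) {
    specs <- specs[[1]]
  }
  if (length(specs) == 0L) abort_field("specs", "empty search space")
  stopifnot(all(vapply(specs, inherits, TRUE, "hyperparam_spec")))
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(list(specs = specs,
                 D = sum(vapply(specs, `[[`, 1L, "D_c"))),
            class = "search_space")
}

#' @rdname search_space
#' @param space a `search_space`.
#' @export
space_dimension <- function(space) {
  if (!inherits(space, "search_space")) abort_field("space", "not a search_space")
  space$D
}

round_half_up <- function(x) floor(x + 0.5)

#' Decode a genome into a configuration
#'
#' Continuous genes map affinely onto `[lo, hi]`; integer genes likewise,
#' then round half-up and clip; categorical sub-vectors select the option at
#' the argmax position (ties broken toward the first option). Decoding is
#' total: every genome in `[0, 1]^D` yields a valid configuration, and the
#' categorical rule is invariant under any strictly increasing transform of
#' the sub-vector.
#'
#' @param genome numeric vector in `[0, 1]^D`.
#' @param space a [search_space()].
#' @return Named list of decoded parameter values.
#' @examples
#' sp <- search_space(
#'   param_integer("batch_size", 16, 512),
#'   param_categorical("activation", c("relu", "tanh"))
#' )
#' decode_genome(c(0.5, 0.2, 0.9), sp)
#' @export
decode_genome <- function(genome, space) {
  if (!inherits(space, "search_space")) abort_field("space", "not a search_space")
  if (length(genome) != space$D) {
    abort_field("genome", sprintf("length %d, expected D = %d",
                                  length(genome), space$D))
  }
  if (any(!is.finite(genome)) || any(genome < 0) || any(genome > 1)) {
    abort_field("genome", "entries must lie in [0, 1]")
  }
  out <- list()
  pos <- 1L
  for (sp in space$specs) {
    g <- genome[seq.int(pos, length.out = sp$D_c)]
    pos <- pos + sp$D_c
    out[[sp$name]] <- switch(sp$kind,
      continuous = sp$lo + g * (sp$hi - sp$lo),
      integer = {
        v <- round_half_up(sp$lo + g * (sp$hi - sp$lo))
        as.integer(min(max(v, sp$lo), sp$hi))
      },
      categorical = sp$options[which.max(g)]
    )
  }
  out
}

#' Published search-space presets
#'
#' The generator space covers batch size, epochs, learning rate, activation
#' (five options), dropout, MLP depth, noise size and the reconstruction
#' weight lambda; the discriminator space swaps noise size/lambda for the
#' consistency and pseudo-label weights. Ranges follow the published search
#' table; the dropout upper bound is 0.95 because a rate of 1 is invalid.
#'
#' @return A [search_space()].
#' @export
table2_generator_space <- function() {
  search_space(
    param_integer("batch_size", 16, 512),
    param_integer("epochs", 64, 1024),
    param_continuous("learning_rate", 1e-5, 1),
    param_categorical("activation",
                      c("relu", "leaky_relu", "linear", "tanh", "sigmoid")),
    param_continuous("dropout_rate", 0, 0.95),
    param_integer("n_layers", 1, 10),
    param_integer("noise_size", 16, 1024),
    param_continuous("lambda", 0, 1)
  )
}

#' @rdname table2_generator_space
#' @export
desk_generator_space <- function() {
  # CPU-sized restriction of the generator space used by the desk-scale
  # tuner: same parameters, ranges narrowed so a short-budget training run
  # per evaluation stays cheap
  search_space(
    param_integer("batch_size", 16, 128),
    param_continuous("learning_rate", 1e-4, 5e-2),
    param_categorical("activation",
                      c("relu", "leaky_relu", "linear", "tanh", "sigmoid")),
    param_continuous("dropout_rate", 0, 0.5),
    param_integer("n_layers", 1, 4),
    param_integer("noise_size", 16, 64),
    param_continuous("lambda", 0, 1)
  )
}

#' @rdname table2_generator_space
#' @export
table2_discriminator_space <- function() {
  search_space(
    param_integer("batch_size", 16, 512),
    param_integer("epochs", 64, 1024),
    param_continuous("learning_rate", 1e-5, 1),
    param_categorical("activation",
                      c("relu", "leaky_relu", "linear", "tanh", "sigmoid")),
    param_continuous("dropout_rate", 0, 0.95),
    param_integer("n_layers", 1, 10),
    param_continuous("lambda_consistency", 0, 1),
    param_continuous("lambda_pseudo", 0, 1)
  )
}
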