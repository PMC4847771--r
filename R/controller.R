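# Controller architecture: 6 inputs -> 10 hidden <-> 10 context -> 3 outputs.
# 60 + 100 + 100 + 30 = 290 weights, one gene per weight, genes in [0,1]
# mapped affinely onto weights in [-1,1].

N_INPUT <- 6L
N_HIDDEN <- 10L
N_CONTEXT <- 10L
N_OUTPUT <- 3L

#' Genotype length
#'
#' Number of genes (= number of controller weights): `6*10 + 10*10 + 10*10 +
#' 10*3 = 290`.
#'
#' @return Integer scalar, 290.
#' @export
genotype_length <- function() {
  N_INPUT * N_HIDDEN + N_CONTEXT * N_HIDDEN + N_HIDDEN * N_CONTEXT +
    N_HIDDEN * N_OUTPUT
}

#' Random genotypes
#'
#' Draws genotypes with i.i.d. `U(0, 1)` genes, the initial condition of an
#' evolutionary run.
#'
#' @param n Number of genotypes.
#' @return If `n == 1` a numeric vector of length 290, otherwise an
#'   `n x 290` matrix (one genotype per row).
#' @export
random_genotype <- function(n = 1) {
  g <- matrix(runif(n * genotype_length()), nrow = n)
  if (n == 1) drop(g) else g
}

validate_genotype <- function(g) {
  if (!is.numeric(g) || length(g) != genotype_length()) {
    stop("genotype must be a numeric vector of length ", genotype_length())
  }
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1)) {
    stop("genes must be finite values in [0, 1]")
  }
  invisible(g)
}

#' Decode a genotype into controller weights
#'
#' Genes are consumed in a fixed row-major order: input-to-hidden (`W_IH`,
#' 6 x 10), context-to-hidden (`W_CH`, 10 x 10), hidden-to-context (`W_HC`,
#' 10 x 10), hidden-to-output (`W_HO`, 10 x 3).  Each gene `x` in \[0, 1\]
#' maps to the weight `2 x - 1` in \[-1, 1\].
#'
#' @param g Numeric genotype of length 290.
#' @return A list of class `controller_weights` with elements `W_IH`, `W_CH`,
#'   `W_HC`, `W_HO`.
#' @examples
#' w <- decode_genotype(rep(0.5, genotype_length()))
#' all(w$W_IH == 0)
#' @export
decode_genotype <- function(g) {
  validate_genotype(g)
  w <- 2 * g - 1
  i <- 0L
  take <- function(nr, nc) {
    m <- matrix(w[(i + 1L):(i + nr * nc)], nrow = nr, ncol = nc, byrow = TRUE)
    i <<- i + nr * nc
    m
  }
  structure(list(W_IH = take(N_INPUT, N_HIDDEN),
                 W_CH = take(N_CONTEXT, N_HIDDEN),
                 W_HC = take(N_HIDDEN, N_CONTEXT),
                 W_HO = take(N_HIDDEN, N_OUTPUT)),
            class = "controller_weights")
}

#' Encode controller weights back into a genotype
#'
#' Inverse of [decode_genotype()]: weight `w` in \[-1, 1\] maps to the gene
#' `(w + 1) / 2`.
#'
#' @param w A `controller_weights` list.
#' @return Numeric genotype of length 290.
#' @export
encode_weights <- function(w) {
  stopifnot(inherits(w, "controller_weights") || is.list(w))
  flat <- c(t(w$W_IH), t(w$W_CH), t(w$W_HC), t(w$W_HO))
  if (any(flat < -1) || any(flat > 1)) stop("weights must lie in [-1, 1]")
  (flat + 1) / 2
}

#' Initial controller state
#'
#' Hidden and context activations all start at `sigma(0) = 0.5`.
#'
#' @return A list with numeric elements `hidden` and `context`.
#' @export
initial_controller_state <- function() {
  list(hidden = rep(0.5, N_HIDDEN), context = rep(0.5, N_CONTEXT))
}

sigmoid <- function(x, beta = 1) 1 / (1 + exp(-beta * x))

#' Advance the recurrent controller by one step
#'
#' Elman-style update: the hidden layer reads the six sensor inputs and the
#' context layer, the three outputs read the new hidden layer, and the context
#' layer is refreshed from the new hidden layer (all through the logistic
#' activation):
#' \deqn{h' = \sigma(W_{IH}^T I + W_{CH}^T c), \quad
#'       O  = \sigma(W_{HO}^T h'), \quad
#'       c' = \sigma(W_{HC}^T h').}
#'
#' @param w `controller_weights` from [decode_genotype()].
#' @param state Controller state list as from [initial_controller_state()].
#' @param inputs Six sensor values in \[0, 1\].
#' @param cfg [controller_config()].
#' @return A list with `outputs` (length 3, each in (0, 1)) and `state` (the
#'   new hidden/context activations).
#' @examples
#' w <- decode_genotype(rep(0.5, genotype_length()))  # all-zero weights
#' step_controller(w, initial_controller_state(), rep(0, 6))$outputs
#' @export
step_controller <- function(w, state, inputs, cfg = controller_config()) {
  if (length(inputs) != N_INPUT || any(!is.finite(inputs))) {
    stop("`inputs` must be 6 finite sensor values")
  }
  beta <- cfg$beta
  hidden <- sigmoid(colSums(inputs * w$W_IH) + colSums(state$context * w$W_CH),
                    beta)
  outputs <- sigmoid(colSums(hidden * w$W_HO), beta)
  context <- sigmoid(colSums(hidden * w$W_HC), beta)
  list(outputs = outputs, state = list(hidden = hidden, context = context))
}

#' Mutate a genotype
#'
#' Each gene is independently mutated with probability `rate` by adding a
#' uniform offset in `[-max_offset, max_offset]`, then clipped back to
#' \[0, 1\].  The parent genotype is not modified.
#'
#' @param g Genotype (numeric, length 290).
#' @param rate Per-gene mutation probability.
#' @param max_offset Half-width of the uniform offset.
#' @return The mutated genotype.
#' @export
mutate_genotype <- function(g, rate = 0.05, max_offset = 0.05) {
  validate_genotype(g)
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop("`rate` must be a probability in [0, 1]")
  }
  n <- length(g)
  hit <- runif(n) < rate
  off <- runif(n, -max_offset, max_offset)
  out <- g
  out[hit] <- pmin(pmax(g[hit] + off[hit], 0), 1)
  out
}

#' Gene positions encoding the hidden-to-signal-output weights
#'
#' Indices (1-based) of the 10 genes that decode to the weights from the
#' hidden layer onto the signal output `O3`.  These are the genes edited when
#' freeriders are injected.
#'
#' @return Integer vector of length 10.
#' @export
o3_gene_indices <- function() {
  offset <- N_INPUT * N_HIDDEN + N_CONTEXT * N_HIDDEN + N_HIDDEN * N_CONTEXT
  offset + (seq_len(N_HIDDEN) - 1L) * N_OUTPUT + N_OUTPUT
}
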