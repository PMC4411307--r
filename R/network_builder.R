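#' Specification of a balanced recurrent network
#'
#' Describes a sparse random excitatory/inhibitory network plus an input
#' layer.  Recurrent connectivity (E-E, E-I, I-E, I-I) is random sparse with
#' probability `p_rec` (no self-connections).  Afferent input connectivity
#' is either receptive-field structured (`mode = "rf"`: each excitatory
#' neuron receives all input units within Euclidean radius `radius` of a
#' uniformly random centre on the input grid, centres clipped so the disc
#' fits) or random sparse (`mode = "sparse"` at probability `p`).
#'
#' The full-scale system of the reference simulations has 4096 excitatory
#' and 1024 inhibitory neurons at 10\% recurrent connectivity with a 64 x 64
#' input grid and radius 8; the desk-scale default here is 1024/256 with the
#' same probabilities.
#'
#' @param n_exc,n_inh population sizes.
#' @param p_rec recurrent connection probability.
#' @param input list describing the input layer: either
#'   `list(mode = "rf", grid = c(64, 64), radius = 8)` or
#'   `list(mode = "sparse", n_input = 4096, p = 0.05)`.
#' @param weights named list of initial weights per connection class:
#'   `input_e`, `e_e`, `e_i`, `i_e`, `i_i`.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(n_exc = 1024, n_inh = 256, p_rec = 0.1,
                         input = list(mode = "rf", grid = c(64, 64),
                                      radius = 8),
                         weights = list(input_e = 0.2, e_e = 0.1,
                                        e_i = 0.1, i_e = 0.3, i_i = 0.3)) {
  stopifnot(n_exc >= 1, n_inh >= 0, p_rec >= 0, p_rec <= 1)
  if (input$mode == "rf") {
    if (2 * input$radius >= min(input$grid))
      stop("receptive-field radius exceeds the input grid")
    input$n_input <- prod(input$grid)
  } else if (input$mode == "sparse") {
    stopifnot(!is.null(input$n_input), input$p > 0, input$p <= 1)
  } else stop("unknown input mode")
  structure(list(n_exc = n_exc, n_inh = n_inh, p_rec = p_rec,
                 input = input, weights = weights),
            class = "network_spec")
}

## directed sparse edge sample: for each post, Binomial(n_pre, p) distinct
## presynaptic partners (self excluded when pops coincide)
.sample_edges <- function(n_pre, n_post, p, exclude_self = FALSE) {
  if (p <= 0) return(list(pre = integer(0), post = integer(0)))
  pre_all <- vector("list", n_post)
  n_avail <- n_pre - as.integer(exclude_self)
  counts <- stats::rbinom(n_post, n_avail, p)
  for (i in seq_len(n_post)) {
    k <- counts[i]
    if (k == 0) { pre_all[[i]] <- integer(0); next }
    cand <- sample.int(n_avail, k)
    if (exclude_self) cand <- ifelse(cand >= i, cand + 1L, cand)
    pre_all[[i]] <- cand - 1L
  }
  list(pre = unlist(pre_all),
       post = rep(seq_len(n_post) - 1L, lengths(pre_all)))
}

#' Build the populations and connections of a balanced network
#'
#' Samples the random sparse connectivity of a [network_spec()] and returns
#' the edge lists per connection class, ready to be attached to plasticity
#' rules and simulated.  Every excitatory neuron is guaranteed at least one
#' afferent input synapse.
#'
#' @param spec a [network_spec()] object.
#' @param seed integer seed for the wiring RNG.
#' @return object of class `plastinet_network`: list with `spec`, `seed`,
#'   `n_exc`, `n_inh`, `n_input`, `rf_centres` (matrix, RF mode only) and
#'   `edges`, a named list (`input_e`, `e_e`, `e_i`, `i_e`, `i_i`) of lists
#'   with 0-based `pre`, `post` and initial `w`.
#' @export
build_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ne <- spec$n_exc; ni <- spec$n_inh
  edges <- list()
  w <- spec$weights
  mk <- function(e, w0) list(pre = e$pre, post = e$post,
                             w = rep(w0, length(e$pre)))
  edges$e_e <- mk(.sample_edges(ne, ne, spec$p_rec, exclude_self = TRUE),
                  w$e_e)
  edges$e_i <- mk(.sample_edges(ne, ni, spec$p_rec), w$e_i)
  edges$i_e <- mk(.sample_edges(ni, ne, spec$p_rec), w$i_e)
  edges$i_i <- mk(.sample_edges(ni, ni, spec$p_rec, exclude_self = TRUE),
                  w$i_i)
  rf_centres <- NULL
  if (spec$input$mode == "rf") {
    g <- spec$input$grid; R <- spec$input$radius
    nx <- g[1]; ny <- g[2]
    cx <- stats::runif(ne, R + 1, nx - R)
    cy <- stats::runif(ne, R + 1, ny - R)
    rf_centres <- cbind(x = cx, y = cy)
    xs <- rep(seq_len(nx), times = ny)
    ys <- rep(seq_len(ny), each = nx)
    pre_all <- vector("list", ne)
    for (i in seq_len(ne)) {
      sel <- which((xs - cx[i])^2 + (ys - cy[i])^2 <= R^2)
      pre_all[[i]] <- sel - 1L
    }
    edges$input_e <- mk(list(pre = unlist(pre_all),
                             post = rep(seq_len(ne) - 1L,
                                        lengths(pre_all))),
                        w$input_e)
  } else {
    repeat {
      e <- .sample_edges(spec$input$n_input, ne, spec$input$p)
      if (length(unique(e$post)) == ne) break  # every neuron >= 1 afferent
    }
    edges$input_e <- mk(e, w$input_e)
  }
  structure(list(spec = spec, seed = seed, n_exc = ne, n_inh = ni,
                 n_input = spec$input$n_input, rf_centres = rf_centres,
                 edges = edges),
            class = "plastinet_network")
}

#' Preset stronger weights inside a cell assembly
#'
#' Sets all existing recurrent E-E synapses with both endpoints in
#' `members` to `w_strong` (used by the embedded-assembly demonstrations).
#'
#' @param net a [build_network()] object.
#' @param members 0-based excitatory neuron ids.
#' @param w_strong weight value for intra-assembly synapses.
#' @return the network with modified `edges$e_e$w`.
#' @export
embed_assembly <- function(net, members, w_strong) {
  stopifnot(inherits(net, "plastinet_network"))
  if (length(members) == 0) return(net)
  if (any(members < 0 | members >= net$n_exc)) stop("unknown neuron ids")
  ee <- net$edges$e_e
  sel <- ee$pre %in% members & ee$post %in% members
  net$edges$e_e$w[sel] <- w_strong
  net
}
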