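#' Build random network connectivity
#'
#' Independent Bernoulli draws per ordered source/target pair for each
#' projection of the balanced network, with autapses excluded on the
#' recurrent E-to-E and I-to-I projections and at most one synapse per
#' ordered pair per compartment. The external Poisson pool is shared:
#' Poisson-to-E and Poisson-to-I fan-outs are independent draws from the
#' same `N_poisson` source processes. All recurrent projections use
#' `p_connect` except E-to-E perisomatic synapses (`p_EE_soma`).
#'
#' @param net a [network_params()] object.
#' @param seed integer seed; the same seed reproduces the same wiring.
#' @return A list of class `"connectivity"` with one element per
#'   projection (`pe`, `pi`, `ee_soma`, `ee_dend`, `ei`, `ie_soma`,
#'   `ie_dend`, `ii`), each a list with 1-based integer vectors `src`,
#'   `tgt` and scalar `w` (nS), plus `net` echoing the parameters.
#' @export
build_connectivity <- function(net, seed = 1L) {
  stopifnot(inherits(net, "network_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  proj <- function(n_src, n_tgt, p, w, no_autapse = FALSE) {
    if (p <= 0) return(list(src = integer(0), tgt = integer(0), w = w))
    hit <- which(stats::runif(n_src * n_tgt) < p)
    src <- ((hit - 1L) %% n_src) + 1L
    tgt <- ((hit - 1L) %/% n_src) + 1L
    if (no_autapse) {
      keep <- src != tgt
      src <- src[keep]; tgt <- tgt[keep]
    }
    o <- order(src, tgt)
    list(src = src[o], tgt = tgt[o], w = w)
  }

  # fixed draw order => reproducibility and condition isolation
  conn <- list(
    pe      = proj(net$N_poisson, net$N_E, net$p_connect, net$w_EP),
    pi      = proj(net$N_poisson, net$N_I, net$p_connect, net$w_IP),
    ee_soma = proj(net$N_E, net$N_E, net$p_EE_soma, net$w_EE,  no_autapse = TRUE),
    ee_dend = proj(net$N_E, net$N_E, net$p_connect, net$w_EE_d, no_autapse = TRUE),
    ei      = proj(net$N_E, net$N_I, net$p_connect, net$w_IE),
    ie_soma = proj(net$N_I, net$N_E, net$p_connect, net$w_EI),
    ie_dend = proj(net$N_I, net$N_E, net$p_connect, net$w_EI_d),
    ii      = proj(net$N_I, net$N_I, net$p_connect, net$w_II, no_autapse = TRUE)
  )
  conn$net <- net
  structure(conn, class = "connectivity")
}

#' Generate shared-pool Poisson input spikes
#'
#' Independent homogeneous Poisson processes, one per source; the count of
#' each source is Poisson(rate * duration) and spike times are uniform on
#' the duration, returned sorted.
#'
#' @param n_sources number of source processes.
#' @param rate rate per source (Hz).
#' @param duration duration (s).
#' @param seed integer seed.
#' @return A list of class `"input_spikes"` with sorted `time` (ms),
#'   matching `source` (1-based), and `duration` (ms), `rate`, `n_sources`.
#' @export
generate_poisson <- function(n_sources, rate, duration, seed = 1L) {
  if (rate < 0 || duration < 0)
    stop("generate_poisson: rate and duration must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  dur_ms <- duration * 1000
  counts <- stats::rpois(n_sources, rate * duration)
  total <- sum(counts)
  time <- stats::runif(total, 0, dur_ms)
  source <- rep.int(seq_len(n_sources), counts)
  o <- order(time)
  structure(list(time = time[o], source = source[o],
                 duration = dur_ms, rate = rate, n_sources = n_sources),
            class = "input_spikes")
}

#' Reduced-scale network fixture
#'
#' Scales the default network down for desk-scale runs: population sizes
#' shrink by `scale` while recurrent synaptic weights grow by `1/scale`,
#' preserving the mean recurrent input `p * N * w` and hence the balanced
#' operating point. The external Poisson pool (1000 sources at 2 Hz, fan-out
#' probability 0.1) is kept at full strength. `scale = 1` is the default
#' network verbatim. The rescaling convention is a testing device, not part
#' of the model.
#'
#' The plasticity parameters (in particular the weight cap `w_max`) are
#' left untouched: the fixture convention rescales only the wiring.
#'
#' @param scale factor in (0, 1].
#' @return A [network_params()] object with a `weight_scale` field
#'   recording the `1/scale` factor applied to recurrent weights.
#' @export
make_fixture <- function(scale = 1) {
  if (scale <= 0 || scale > 1) stop("make_fixture: scale must be in (0, 1]")
  base <- network_params()
  net <- network_params(
    N_E = round(base$N_E * scale), N_I = round(base$N_I * scale),
    N_poisson = base$N_poisson, rate_poisson = base$rate_poisson,
    p_connect = base$p_connect, p_EE_soma = base$p_EE_soma,
    w_EP = base$w_EP, w_IP = base$w_IP,
    w_EE = base$w_EE / scale, w_EE_d = base$w_EE_d / scale,
    w_IE = base$w_IE / scale, w_II = base$w_II / scale,
    w_EI = base$w_EI / scale, w_EI_d = base$w_EI_d / scale)
  net$weight_scale <- 1 / scale
  net
}

#' Write / read plain-text spike files
#'
#' Two-column whitespace-separated text: time in ms, then the 1-based
#' source/neuron id.
#'
#' @param spikes a list with `time` and `source` (or `neuron`) vectors.
#' @param path file path.
#' @return `read_spikes` returns a data.frame with `time` and `source`.
#' @export
write_spikes <- function(spikes, path) {
  id <- if (!is.null(spikes$source)) spikes$source else spikes$neuron
  utils::write.table(data.frame(time = spikes$time, source = id),
                     path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.table(path, col.names = c("time", "source"))
  df$source <- as.integer(df$source)
  df
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
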