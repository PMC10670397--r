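# Cardiorespiratory-interaction (CRI) feature family: the respiratory
# amplitude sampled at each R-peak time, mapped to a natural visibility graph
# and summarized by 8 network features per epoch.

cri_feature_names <- c("vg_degree_mean", "vg_degree_sd", "dvg_degree_mean",
                       "dvg_degree_sd", "vg_assortativity", "vg_cc_mean",
                       "vg_cc_sd", "vg_degree_sampen")

#' Build the CRI series for one epoch
#'
#' Linear interpolation of the respiratory signal at each R-peak time. R
#' times outside the signal span are dropped with a warning.
#'
#' @param r_times R-peak times within the epoch, seconds from epoch start.
#' @param resp respiratory samples for the epoch.
#' @param fs_resp respiration sampling rate, Hz.
#' @return list with \code{times} and \code{values}.
#' @export
build_cri <- function(r_times, resp, fs_resp) {
  tt <- (seq_along(resp) - 1) / fs_resp
  # the sampled span is [0, n/fs): times past the last sample but inside the
  # span take the last sample's value
  ok <- r_times >= 0 & r_times < length(resp) / fs_resp
  if (any(!ok)) {
    warning(sum(!ok), " R time(s) outside the respiratory signal span dropped")
    r_times <- r_times[ok]
  }
  list(times = r_times, values = approx(tt, resp, xout = r_times, rule = 2)$y)
}

#' Natural visibility graph of a time series
#'
#' Nodes are samples in temporal order; nodes a < b are connected iff every
#' intermediate sample lies strictly below the straight line joining them
#' (strict criterion: collinear points block visibility). Consecutive nodes
#' are always connected, so the graph contains a path backbone.
#'
#' @param times strictly increasing sample times.
#' @param values sample values.
#' @return an object of class \code{vis_graph}: \code{n}, a 2-column edge
#'   matrix (1-based, a < b), and the \code{degree} sequence in temporal
#'   order.
#' @export
natural_visibility_graph <- function(times, values) {
  n <- length(times)
  stopifnot(n >= 2, length(values) == n, all(diff(times) > 0))
  edges <- .nvg_edges(as.numeric(times), as.numeric(values))
  structure(list(n = n, edges = edges,
                 degree = tabulate(c(edges[, 1], edges[, 2]), nbins = n)),
            class = "vis_graph")
}

#' Differencing visibility graph
#'
#' Natural visibility graph of the first-differenced series (value
#' \code{x[i+1] - x[i]} placed at time \code{t[i+1]}).
#'
#' @inheritParams natural_visibility_graph
#' @export
differencing_visibility_graph <- function(times, values) {
  stopifnot(length(values) >= 3)
  natural_visibility_graph(times[-1], diff(values))
}

#' Degree statistics of a visibility graph
#'
#' @param g a \code{vis_graph}.
#' @return numeric \code{c(mean, sd)} of the degree sequence.
#' @export
degree_statistics <- function(g) {
  c(mean = mean(g$degree), sd = sd(g$degree))
}

#' Degree assortativity coefficient
#'
#' Newman's degree assortativity: the Pearson correlation of endpoint degrees
#' over all edges, counting both orientations. Missing when the endpoint
#' degree variance is zero (e.g. a regular graph).
#'
#' @param g a \code{vis_graph} with at least 2 edges.
#' @return value in [-1, 1], or \code{NA}.
#' @export
assortativity <- function(g) {
  if (nrow(g$edges) < 2) return(NA_real_)
  du <- g$degree[c(g$edges[, 1], g$edges[, 2])]
  dv <- g$degree[c(g$edges[, 2], g$edges[, 1])]
  if (sd(du) == 0 || sd(dv) == 0) return(NA_real_)
  stats::cor(du, dv)
}

#' Local clustering coefficient statistics
#'
#' Per-node clustering coefficient (realized triangles over neighbor pairs;
#' 0 for degree < 2), summarized by mean and SD across nodes.
#'
#' @param g a \code{vis_graph} with at least 3 nodes.
#' @return numeric \code{c(mean, sd)}, each in [0, 1].
#' @export
clustering_statistics <- function(g) {
  n <- g$n
  adj <- vector("list", n)
  for (e in seq_len(nrow(g$edges))) {
    a <- g$edges[e, 1]; b <- g$edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  amat <- matrix(FALSE, n, n)
  amat[g$edges] <- TRUE
  amat[g$edges[, 2:1, drop = FALSE]] <- TRUE
  cc <- vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(amat[nb, nb, drop = FALSE]) / 2
    tri / (k * (k - 1) / 2)
  }, 0.0)
  c(mean = mean(cc), sd = sd(cc))
}

#' Sample entropy of the degree sequence
#'
#' SampEn (m = 2, r = 0.2 SD) of the visibility-graph degrees taken in node
#' (temporal) order; 0 for a regular graph.
#'
#' @param g a \code{vis_graph} with more than 3 nodes.
#' @param m,r_frac sample-entropy parameters.
#' @export
degree_sample_entropy <- function(g, m = 2, r_frac = 0.2) {
  d <- as.numeric(g$degree)
  if (length(d) <= m + 1) return(NA_real_)
  s <- sd(d)
  if (s == 0) return(0)
  sample_entropy(d, m, r_frac * s)
}

#' Extract the 8 CRI network features for one epoch
#'
#' VG degree mean/SD, DVG degree mean/SD, assortativity, clustering mean/SD,
#' and degree sample entropy, all on the natural visibility graph of the CRI
#' series (real R-peak times as the time axis by default).
#'
#' @param epoch an epoch from [epochize()].
#' @param config a [feature_config()].
#' @return named numeric vector of length 8; all \code{NA} with fewer than
#'   \code{config$cri_min_beats} R peaks.
#' @export
extract_cri <- function(epoch, config = feature_config()) {
  v <- setNames(rep(NA_real_, length(cri_feature_names)), cri_feature_names)
  if (length(epoch$rpeaks) < config$cri_min_beats) return(v)
  cri <- build_cri(epoch$rpeaks, epoch$resp, epoch$fs_resp)
  if (length(cri$times) < config$cri_min_beats) return(v)
  tx <- if (config$vg_time_axis == "real") cri$times
        else seq_along(cri$values)
  g <- natural_visibility_graph(tx, cri$values)
  dg <- differencing_visibility_graph(tx, cri$values)
  ds <- degree_statistics(g)
  dds <- degree_statistics(dg)
  cs <- clustering_statistics(g)
  v["vg_degree_mean"] <- ds["mean"]; v["vg_degree_sd"] <- ds["sd"]
  v["dvg_degree_mean"] <- dds["mean"]; v["dvg_degree_sd"] <- dds["sd"]
  v["vg_assortativity"] <- assortativity(g)
  v["vg_cc_mean"] <- cs["mean"]; v["vg_cc_sd"] <- cs["sd"]
  v["vg_degree_sampen"] <- degree_sample_entropy(g, config$sampen_m,
                                                 config$sampen_r_frac)
  v
}
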