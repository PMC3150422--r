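#' Superoxide generation by respiration
#'
#' Each simulation step a mitochondrion undergoes a Poisson number of
#' respiration events with mean `respiration_rate * size` (size = pixel
#' area by default). Each event independently leaks one O2- agent with the
#' probability given by the electron-leakage rule evaluated at the
#' mitochondrion's current internal ROS load; leaked agents appear
#' uniformly at random inside the mitochondrion's rectangle.
#'
#' @param mito one-row data.frame (a row of `geometry$mito`).
#' @param n_h2o2,n_o2 current internal ROS agent counts.
#' @param params a [sim_params()].
#' @return numeric matrix (k x 2) of new O2- positions, possibly 0-row.
#' @export
respire <- function(mito, n_h2o2, n_o2, params) {
  size <- mito_size(mito, params$respiration_size)
  ev <- stats::rpois(1L, params$respiration_rate * size)
  if (ev == 0) return(matrix(numeric(0), ncol = 2))
  p <- leakage_probability(n_h2o2, n_o2, params$leak, area = mito$w * mito$h)
  k <- stats::rbinom(1L, ev, p)
  if (k == 0) return(matrix(numeric(0), ncol = 2))
  cbind(stats::runif(k, mito$x, mito$x + mito$w),
        stats::runif(k, mito$y, mito$y + mito$h))
}

mito_size <- function(mito, mode) {
  if (mode == "length") mito$h else mito$w * mito$h
}

# Vectorized respiration over all mitochondria; returns list(pos, n).
respire_all <- function(geometry, n_h2o2, n_o2, params) {
  m <- geometry$mito
  nm <- nrow(m)
  if (nm == 0) return(list(pos = matrix(numeric(0), ncol = 2), n = 0L))
  sizes <- mito_size(m, params$respiration_size)
  ev <- stats::rpois(nm, params$respiration_rate * sizes)
  p <- leakage_probability(n_h2o2, n_o2, params$leak, area = m$w * m$h)
  k <- stats::rbinom(nm, ev, p)
  tot <- sum(k)
  if (tot == 0) return(list(pos = matrix(numeric(0), ncol = 2), n = 0L))
  idx <- rep.int(seq_len(nm), k)
  pos <- cbind(stats::runif(tot, m$x[idx], m$x[idx] + m$w[idx]),
               stats::runif(tot, m$y[idx], m$y[idx] + m$h[idx]))
  list(pos = pos, n = tot)
}

#' Classify reactive mitochondria
#'
#' A mitochondrion is reactive when its internal O2- agent count strictly
#' exceeds the threshold (default: more than 50 agents).
#'
#' @param o2_counts integer vector of internal O2- counts, one per
#'   mitochondrion.
#' @param threshold reactivity threshold (strict).
#' @return list with `reactive` (logical vector) and `fraction`
#'   (percentage of reactive mitochondria).
#' @export
#' @examples
#' classify_reactive(c(50, 51, 0))  # 1/3 reactive
classify_reactive <- function(o2_counts, threshold = 50) {
  if (length(o2_counts) == 0)
    stop("cannot compute a reactive fraction with no mitochondria")
  stopifnot(all(o2_counts >= 0))
  reactive <- o2_counts > threshold
  list(reactive = reactive, fraction = 100 * mean(reactive))
}
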