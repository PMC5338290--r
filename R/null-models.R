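#' Degree-preserving randomization and Z-score machinery
#'
#' Every significance statement in the package compares an observed network
#' statistic against its distribution over randomized networks that keep the
#' degree structure of the data. Two null models are provided:
#' `fixed_fixed` keeps both degree sequences exactly (checkerboard/curveball
#' exchanges over the incidence matrix, backed by the \pkg{vegan} null-model
#' engine), and `probabilistic` fills each cell independently with
#' probability proportional to the product of the endpoint degrees, so that
#' degrees are preserved in expectation only.
#'
#' @name null-models
NULL

.netFromIncidence <- function(M) {
  idx <- which(M > 0, arr.ind = TRUE)
  new("PlantHerbivoreNetwork",
      insects = rownames(M), plants = colnames(M),
      edges = data.frame(insect = rownames(M)[idx[, 1]],
                         plant = colnames(M)[idx[, 2]],
                         stringsAsFactors = FALSE))
}

.cellProbabilities <- function(M) {
  m <- sum(M)
  p <- outer(rowSums(M), colSums(M)) / m
  pmin(p, 1)
}

# Array of null incidence matrices (nr x nc x replicates).
.nullArray <- function(M, config) {
  R <- config@replicates
  if (config@model == "fixed_fixed") {
    if (sum(M) < 2L || nrow(M) < 2L || ncol(M) < 2L) {
      arr <- array(rep(M, R), dim = c(dim(M), R))
      dimnames(arr) <- c(dimnames(M), list(NULL))
      return(arr)
    }
    burn <- config@swapsPerEdge * sum(M)
    sim <- stats::simulate(vegan::nullmodel(M, "curveball"),
                           nsim = R, burnin = burn, thin = burn,
                           seed = config@seed)
    arr <- array(as.numeric(sim), dim = dim(sim))
    dimnames(arr) <- c(dimnames(M), list(NULL))
    arr
  } else {
    p <- .cellProbabilities(M)
    set.seed(config@seed)
    arr <- array(stats::rbinom(length(p) * R, 1L, rep(as.vector(p), R)),
                 dim = c(dim(M), R))
    dimnames(arr) <- c(dimnames(M), list(NULL))
    arr
  }
}

#' Randomize a network preserving both degree sequences exactly
#'
#' Runs a chain of checkerboard (2x2 submatrix) exchanges on the bipartite
#' incidence matrix; every accepted exchange preserves all row and column
#' sums, so the returned network has degree sequences identical to the
#' input's. Networks admitting no exchange (e.g. complete bipartite) are
#' returned unchanged with a note.
#'
#' @param net a [PlantHerbivoreNetwork-class] with at least 2 edges.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param swapsPerEdge attempted exchanges per edge used as burn-in.
#' @return a randomized [PlantHerbivoreNetwork-class].
#' @export
randomizeFixedFixed <- function(net, seed = 1L, swapsPerEdge = 10L) {
  if (nEdges(net) < 2L) stop("need at least 2 edges to randomize")
  M <- asIncidenceMatrix(net)
  if (nrow(M) < 2L || ncol(M) < 2L) {
    message("no degree-preserving exchange possible; returning input")
    return(net)
  }
  cfg <- nullModelConfig("fixed_fixed", replicates = 1L, seed = seed,
                         swapsPerEdge = swapsPerEdge)
  out <- .netFromIncidence(.nullArray(M, cfg)[, , 1])
  if (identical(sort(paste(out@edges$insect, out@edges$plant)),
                sort(paste(net@edges$insect, net@edges$plant))) &&
      prod(dim(M)) == sum(M))
    message("network is complete bipartite; no exchange possible")
  out
}

#' Randomize a network by the degree-product probabilistic null model
#'
#' Each insect-plant cell is filled independently with probability
#' `min(1, d_i * d_j / m)` where `d_i`, `d_j` are the observed degrees and
#' `m` the observed edge count, so the expected edge count equals `m` and
#' degrees are preserved in expectation.
#'
#' @inheritParams randomizeFixedFixed
#' @return a randomized [PlantHerbivoreNetwork-class].
#' @export
randomizeProbabilistic <- function(net, seed = 1L) {
  if (nEdges(net) < 1L) stop("need at least 1 edge to randomize")
  M <- asIncidenceMatrix(net)
  cfg <- nullModelConfig("probabilistic", replicates = 1L, seed = seed)
  .netFromIncidence(.nullArray(M, cfg)[, , 1])
}

#' Score an observed statistic against null replicate values
#'
#' @param observed observed value of the statistic.
#' @param nullValues numeric vector of the statistic over null replicates.
#' @return a [ZScoreResult-class]; `Z = (observed - mean) / sd` with the
#'   sample standard deviation (denominator n - 1). A null with zero spread
#'   is flagged degenerate and yields `Z = NA` rather than infinity.
#' @examples
#' zScore(3, c(0, 1, 2))  # Z = 2
#' @export
zScore <- function(observed, nullValues) {
  nullValues <- as.numeric(nullValues)
  if (length(nullValues) == 0L) stop("nullValues must be non-empty")
  mu <- mean(nullValues)
  sdv <- if (length(nullValues) > 1L) stats::sd(nullValues) else 0
  degen <- (sdv == 0)
  new("ZScoreResult", observed = as.numeric(observed), nullMean = mu,
      nullSd = sdv, z = if (degen) NA_real_ else (observed - mu) / sdv,
      replicates = length(nullValues), degenerate = degen)
}

#' Null distribution of an arbitrary network statistic
#'
#' @param net a [PlantHerbivoreNetwork-class].
#' @param statistic a function taking a [PlantHerbivoreNetwork-class] and
#'   returning a single number; it must not depend on anything that varies
#'   between replicates other than the network itself.
#' @param config a [NullModelConfig-class].
#' @return numeric vector of length `config@replicates`; fully reproducible
#'   given `config@seed`.
#' @export
nullDistribution <- function(net, statistic, config = nullModelConfig()) {
  arr <- .nullArray(asIncidenceMatrix(net), config)
  vapply(seq_len(dim(arr)[3]), function(r) {
    val <- tryCatch(statistic(.netFromIncidence(arr[, , r])),
                    error = function(e)
                      stop("statistic failed on replicate ", r, ": ",
                           conditionMessage(e), call. = FALSE))
    as.numeric(val)
  }, numeric(1))
}
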