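# Internal vectorized statistics over incidence matrices. These are the hot
# paths shared by the observed-network functions and the null-model tests:
# everything is phrased as matrix products so that scoring 1,000 null
# replicates stays cheap.

# species x taxon 0/1 indicator at a taxonomic level; species whose taxon is
# unknown at that level get an all-zero row (their edges drop out of any
# product).
.taxonIndicator <- function(speciesNames, taxonomy, level) {
  taxa <- taxonOf(taxonomy, speciesNames, level)
  levs <- sort(unique(taxa[!is.na(taxa)]))
  ind <- matrix(0, length(speciesNames), length(levs),
                dimnames = list(speciesNames, levs))
  ok <- !is.na(taxa)
  if (any(ok)) ind[cbind(which(ok), match(taxa[ok], levs))] <- 1
  ind
}

# plant x plant shared-compound count matrix; diagonal holds |C_i|.
.overlapMatrix <- function(catalog, plants) {
  sets <- compoundsOf(catalog, plants)
  if (length(plants) == 1L) sets <- stats::setNames(list(sets), plants)
  compounds <- unique(unlist(sets, use.names = FALSE))
  if (length(compounds) == 0L)
    return(matrix(0, length(plants), length(plants),
                  dimnames = list(plants, plants)))
  ind <- matrix(0, length(plants), length(compounds),
                dimnames = list(plants, compounds))
  for (i in seq_along(plants)) ind[i, match(sets[[i]], compounds)] <- 1
  tcrossprod(ind)
}

# family-based evenness per insect row of M; K is |m_f|, the number of plant
# families present in the whole network. Rows with no family-resolvable host
# return NA. E = 0 for single-family diets and whenever K = 1.
.rowEvenness <- function(M, plantFamInd, K = ncol(plantFamInd)) {
  counts <- M %*% plantFamInd
  S <- rowSums(counts)
  P <- counts / ifelse(S > 0, S, 1)
  H <- -rowSums(ifelse(P > 0, P * log(P), 0))
  E <- if (K > 1) H / log(K) else rep(0, nrow(M))
  E[S == 0] <- NA_real_
  E
}

.evennessFromCounts <- function(counts, K) {
  S <- sum(counts)
  if (S == 0) return(NA_real_)
  if (K <= 1) return(0)
  p <- counts[counts > 0] / S
  -sum(p * log(p)) / log(K)
}

# host counts per plant family for a pooled insect category: distinct host
# plants of the member rows.
.categoryFamilyCounts <- function(M, rows, plantFamInd) {
  u <- as.numeric(colSums(M[rows, , drop = FALSE]) > 0)
  as.vector(crossprod(plantFamInd, u))
}

# food-pairing N_s per insect row: mean shared-compound count over unordered
# host pairs; rows with < 2 hosts are NA (excluded, not zero-filled).
.rowNs <- function(M, O) {
  n <- rowSums(M)
  quad <- rowSums((M %*% O) * M)          # sum_{a,b in hosts} O[a,b]
  diagTerm <- as.vector(M %*% diag(O))    # sum_{a in hosts} O[a,a]
  ns <- (quad - diagTerm) / (n * (n - 1))
  ns[n < 2] <- NA_real_
  ns
}

# compound-contribution chi per plant column of M. T1 averages, over the
# plant's herbivores that have >= 2 hosts, the mean compound overlap between
# the plant and the herbivore's other hosts; T2 is the same average over all
# other plants (the no-selectivity expectation). Plants with no herbivore,
# or none with >= 2 hosts, return NA.
.chiVec <- function(M, O) {
  nP <- ncol(M)
  n <- rowSums(M)
  elig <- as.numeric(n >= 2)
  MO <- M %*% O
  diagO <- diag(O)
  denomK <- ifelse(n >= 2, n - 1, 1)
  ratio <- (MO - matrix(diagO, nrow(M), nP, byrow = TRUE)) / denomK
  wt <- M * elig
  nElig <- colSums(wt)
  T1 <- colSums(ratio * wt) / ifelse(nElig > 0, nElig, 1)
  T2 <- (colSums(O) - diagO) / (nP - 1)
  chi <- T1 - T2
  chi[nElig == 0] <- NA_real_
  chi
}

# per-insect count of distinct host-plant families.
.insectFamilyBreadth <- function(M, plantFamInd) {
  rowSums((M %*% plantFamInd) > 0)
}
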