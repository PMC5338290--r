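# Independent oracles used to check the package implementations. Each is a
# direct transcription of the defining formula, kept free of any package
# internals.

# Shannon-entropy evenness from per-family host counts, normalized by
# log(K) where K is the number of plant families in the whole network.
oracleEvenness <- function(countsByFamily, K) {
  counts <- countsByFamily[countsByFamily > 0]
  if (K <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(K)
}

# food-pairing N_s by explicit enumeration of unordered host pairs.
oracleNs <- function(compoundSets) {
  n <- length(compoundSets)
  stopifnot(n >= 2)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + length(intersect(compoundSets[[i]], compoundSets[[j]]))
  tot / (n * (n - 1) / 2)
}

# two-sided Fisher p by exhaustive enumeration over all 2x2 tables with the
# observed margins; table probabilities from log-binomial coefficients.
oracleFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  pObs <- logp[xs == a]
  sum(exp(logp[logp <= pObs + 1e-7]))
}

# chi (compound contribution) for one plant by direct loops over herbivores
# and host sets.
oracleChi <- function(edges, compoundSets, plant, allPlants) {
  herbs <- unique(edges$insect[edges$plant == plant])
  if (!length(herbs)) return(NA_real_)
  ov <- function(p, q)
    length(intersect(compoundSets[[p]], compoundSets[[q]]))
  t1terms <- numeric(0)
  for (k in herbs) {
    hosts <- unique(edges$plant[edges$insect == k])
    others <- setdiff(hosts, plant)
    if (length(hosts) >= 2)
      t1terms <- c(t1terms, mean(vapply(others, ov, numeric(1), p = plant)))
  }
  if (!length(t1terms)) return(NA_real_)
  others <- setdiff(allPlants, plant)
  t2 <- mean(vapply(others, ov, numeric(1), p = plant))
  mean(t1terms) - t2
}

# small fixture builders -----------------------------------------------------

toyNetwork <- function(pairs) {
  plantHerbivoreNetwork(data.frame(insect = pairs[, 1], plant = pairs[, 2],
                                   stringsAsFactors = FALSE))
}

# taxonomy where plant "P<f>x<k>" belongs to family "Fam<f>"
gridPlantTaxonomy <- function(nFam, perFam) {
  taxonomyMap(data.frame(
    species = as.vector(outer(seq_len(perFam), seq_len(nFam),
                              function(k, f) sprintf("P%dx%d", f, k))),
    family = as.vector(outer(seq_len(perFam), seq_len(nFam),
                             function(k, f) sprintf("Fam%d", f)))),
    side = "plant")
}

writeTempTable <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
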