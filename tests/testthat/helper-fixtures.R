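# In-code fixtures shared across test files.

# Minimal hand-built population: 2 parentA, 2 parentB, 2 F1, 4 markers.
toyPopulation <- function() {
  g <- rbind(
    A1 = c(2, 0, 2, 0),
    A2 = c(0, 0, 2, 2),
    B1 = c(2, 2, 0, 0),
    B2 = c(0, 2, 0, 2),
    H1 = c(2, 1, 1, 0),   # A1 x B1
    H2 = c(0, 1, 1, 2)    # A2 x B2
  )
  colnames(g) <- paste0("M", 1:4)
  NCIIPopulation(
    g,
    roles = c(A1 = "parentA", A2 = "parentA", B1 = "parentB",
              B2 = "parentB", H1 = "F1", H2 = "F1"),
    pedigree = data.frame(f1 = c("H1", "H2"), parentA = c("A1", "A2"),
                          parentB = c("B1", "B2"), stringsAsFactors = FALSE),
    phenotypes = c(A1 = 10, A2 = 12, B1 = 11, B2 = 14, H1 = 13, H2 = 15),
    traitName = "oil"
  )
}

# Write a population's three CSV tables into a fresh temp dir.
toyFiles <- function(pop = toyPopulation()) {
  dir <- tempfile("ncii")
  dir.create(dir)
  writePopulation(pop, dir)
}

# Deterministic simulated population for mapping tests.
simPop <- function(m = 20, nA = 60, nB = 30, nF1 = 110, h2 = 0.08, seed = 11,
                   qtl = defaultQTLArchitecture(m, h2)) {
  spec <- simulationSpec(markers = m, nParentA = nA, nParentB = nB,
                         nF1 = nF1, qtl = qtl)
  simulateNCII(spec, seed = seed)
}
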