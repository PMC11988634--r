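# Independent brute-force oracle for the descriptor core: expands the
# molecule into one entry per atom and accumulates valences in an explicit
# loop; shares no code with the package implementation.
bruteForceDescriptor <- function(counts, valenceMap) {
  atoms <- character(0)
  for (el in names(counts))
    for (k in seq_len(counts[[el]])) atoms <- c(atoms, el)
  total <- 0
  for (a in atoms) total <- total + valenceMap[[a]]
  z <- total / length(atoms)
  e <- 0.25 * (z / (2 * pi)) * sin(1.04 * pi * z)
  list(aqvn = z, eiip = e, nAtoms = length(atoms), qvs = total)
}

defaultValenceMap <- c(H = 1, C = 4, N = 5, O = 6, S = 6, P = 5,
                       F = 1, Cl = 1, Br = 1, I = 1)

# Random composition over elements covered by the default valence table
randomComposition <- function() {
  nEl <- sample(1:6, 1)
  els <- sample(names(defaultValenceMap), nEl)
  stats::setNames(sample(1:60, nEl, replace = TRUE), els)
}

countsToFormula <- function(counts) {
  paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}
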