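# Shared fixtures: loaded once per test run.

# bundled reaction sets (library loads are validated on load)
allRxn <- suppressMessages(bundledReactionLibrary("AllRxn"))
clickRxn <- suppressMessages(bundledReactionLibrary("AutoClickChemRxn"))
robustRxn <- suppressMessages(bundledReactionLibrary("RobustRxn"))

# a small complementary library over the bundled reactant set
compLib <- local({
  path <- system.file("extdata", "complementary_seeds.smi",
                      package = "evoligand")
  smi <- vapply(suppressMessages(readSmi(path)), smiles, "")
  suppressMessages(buildComplementaryLibrary(smi, allRxn))
})

# deterministic fixture seed set covering all functional-group classes
fixtureSeeds <- local({
  set.seed(20240917)
  generateFixtureLibrary(list(alcohol = 4, `carboxylic acid` = 4,
                              `primary amine` = 4, azide = 4,
                              `terminal alkyne` = 4, `aryl halide` = 4))
})

writeFixtureSmi <- function(path = tempfile(fileext = ".smi")) {
  writeLines(paste(fixtureSeeds, paste0("fx", seq_along(fixtureSeeds))),
             path)
  path
}

# find a bundled reaction by name
getReaction <- function(name, lib = allRxn) {
  hit <- Filter(function(r) r@name == name, reactions(lib))
  if (length(hit) == 0L) stop("no bundled reaction called ", name)
  hit[[1]]
}

# random descriptor rows for filter property tests
randomDescriptors <- function(n) {
  data.frame(
    mw = runif(n, 0, 900),
    logp = runif(n, -4, 9),
    hbd = sample(0:9, n, replace = TRUE),
    hba = sample(0:14, n, replace = TRUE),
    mr = runif(n, 10, 180),
    n_atoms = sample(5:90, n, replace = TRUE),
    heavy_atoms = sample(3:60, n, replace = TRUE),
    rotb = sample(0:25, n, replace = TRUE),
    rings = sample(0:9, n, replace = TRUE),
    n_count = sample(0:6, n, replace = TRUE),
    o_count = sample(0:6, n, replace = TRUE),
    x_count = sample(0:9, n, replace = TRUE),
    psa = runif(n, 0, 250))
}

# random sparse bit-set fingerprints
randomFingerprint <- function(nbits = 256L, maxOn = 40L) {
  k <- sample.int(maxOn, 1L)
  new("Fingerprint",
      bits = sort(sample.int(nbits, k) - 1L),
      nbits = nbits, radius = 2L)
}

scoredRecord <- function(smiles, id, primary, diversity = 0) {
  moleculeRecord(smiles, id = id,
                 scores = c(primary = primary, diversity = diversity))
}
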