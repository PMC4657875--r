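# tiny three-species panel for unit tests
toyPanel <- function() {
  act <- matrix(c(2, 4, 6,
                  1, 2, 3,
                  10, 20, 30,
                  100, 200, 300),
                nrow = 3,
                dimnames = list(c("Aa", "Bb", "Cc"), enzymeClasses()))
  SpeciesPanel(species = c("A alpha", "B beta", "C gamma"),
               abbrev = c("Aa", "Bb", "Cc"), intrinsicActivity = act)
}

# toy phenotype matrix: total plate (all grow), cond1 (Aa, Bb), cond2 (Aa);
# Cc carries a distinct colony class
toyPheno <- function() {
  g <- matrix(c(2L, 2L, 2L,   # Aa: total, cond1, cond2
                2L, 2L, 0L,   # Bb
                2L, 0L, 0L),  # Cc
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Aa", "Bb", "Cc"),
                              c("total", "cond1", "cond2")))
  conds <- data.frame(condition = c("total", "cond1", "cond2"),
                      temp = 30, supplement = c("none", "s1", "s2"),
                      stringsAsFactors = FALSE)
  PhenotypeMatrix(g, conds, c(Aa = "white", Bb = "white", Cc = "blue"))
}

# single shared default-seed study run, reused across test files
cachedStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- runStudy(studyConfig(seed = 1L))
    cache
  }
})
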