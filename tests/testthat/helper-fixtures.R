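# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

smallAtlas <- function() fixture("smallAtlas", function() makeAtlas(20, seed = 1))
midAtlas <- function() fixture("midAtlas", function() makeAtlas(100, seed = 1))

smallCohort <- function() fixture("smallCohort", function() makeCohort(3, 3, 4))

# 10 subjects x 3 sessions x 20 parcels on a reduced grid: the workhorse
# profile set for structural tests
smallProfiles <- function() fixture("smallProfiles", function() {
  tr <- makeGroundTruth(smallAtlas(), nGenes = 1, seed = 1)
  simulateProfiles(smallCohort(), smallAtlas(), truth = tr, seed = 7,
                   freq = seq(0, 150, by = 2.5))
})

midSpins <- function() fixture("midSpins", function() {
  generateSpins(midAtlas(), nPerm = 199, seed = 3)
})

# reduced 0-150 Hz grid used where the full 301-bin grid is not the point
coarseFreq <- function() seq(0, 150, by = 2.5)
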