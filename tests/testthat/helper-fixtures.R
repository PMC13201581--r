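# Shared fixtures, built once per test run. Everything is generated in code;
# nothing is read from disk.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixtureEnv)) assign(name, builder(), .fixtureEnv)
  get(name, .fixtureEnv)
}

# a small clean phantom used by many tests
smallPhantom <- function() fixture("smallPhantom", function()
  makePhantom(phantomSpec(shape = c(48, 48, 48), seed = 7)))

# a cohort sharing the small phantom's geometry
smallCohort <- function() fixture("smallCohort", function()
  makeCohort(4, phantomSpec(shape = c(48, 48, 48), seed = 7),
             variability = 1.5))

# an atlas fused from the small cohort (members near-aligned by construction,
# so identity alignment is adequate for unit tests)
smallAtlas <- function() fixture("smallAtlas", function()
  buildAtlas(lapply(smallCohort(), function(m) m[c("ct", "labels")]),
             sigma = 1.0))
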