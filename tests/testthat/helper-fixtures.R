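## Shared fixtures, computed lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

## Two subjects, one arm each: 2 sessions, 36 movement instances.
smallCohort <- function() {
  cached("smallCohort",
         synthCohort(cohortSpec(nSubjects = 2, armsPerSubject = 1,
                                seed = 2024L)))
}

smallSegments <- function() {
  cached("smallSegments",
         unlist(lapply(smallCohort()$sessions, segmentSession),
                recursive = FALSE))
}

## Separable mid-size cohort for classifier tests: 5 subjects x 2 arms =
## 180 instances (30 per class).
classifierCohort <- function() {
  cached("classifierCohort",
         synthCohort(cohortSpec(nSubjects = 5, armsPerSubject = 2,
                                seed = 7L)))
}

classifierDataset <- function(mode = "average") {
  cached(paste0("classifierDataset_", mode), {
    segs <- cached("classifierSegments",
                   unlist(lapply(classifierCohort()$sessions,
                                 segmentSession), recursive = FALSE))
    assembleMatrix(segs, mode = mode)
  })
}

## Independent oracle for the average-of-sequences feature: explicit
## double loop over the literal 1-based band pointers.
naiveAvgSequences <- function(x) {
  vectorFFT <- Mod(stats::fft(x))
  out <- numeric(50)
  startValue <- 5
  endValue <- 130
  for (i in 1:50) {
    acc <- 0
    for (j in startValue:endValue) acc <- acc + vectorFFT[j]
    out[i] <- acc / (endValue - startValue + 1)
    startValue <- startValue + 130
    endValue <- endValue + 130
  }
  out
}

## Shuffle the movement labels of a GestureDataset (seeded).
shuffleLabels <- function(gd, seed) {
  cd <- SummarizedExperiment::colData(gd)
  set.seed(seed)
  cd$movement <- sample(cd$movement)
  SummarizedExperiment::colData(gd) <- cd
  gd
}
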