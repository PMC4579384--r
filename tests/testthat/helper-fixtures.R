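# Shared fixtures, computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    reg <- reference_registry()
    dogs <- suppressMessages(resolve_dogs(reg))
    trio <- suppressMessages(build_trio_cohort(dogs))
    .fixture_env$bundle <- list(
      registry = reg,
      dogs = dogs,
      trio = trio,
      mating = mating_type_table(trio)
    )
  }
  .fixture_env$bundle
}

# Small hand-written registry CSV for I/O tests.
write_mini_registry <- function(path, rows) {
  header <- "dog_id,sex,sire_id,dam_id,litter_id,exam_date,certificate_valid,distichiasis,grade,other_diagnosis"
  writeLines(c(header, rows), path)
  path
}

# Independent Yates oracle from the expected-count definition.
yates_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum(pmax(0, abs(m - e) - 0.5)^2 / e)
}

pearson_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
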