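# Fixtures are generated in code and memoised per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# The standard synthetic study fixture (planted modules, 5% label noise).
studyFixture <- function() memo("study", generateSynthetic(synthConfig(seed = 7L)))

# Tiny graph with hand-listed edges for degree/path assertions:
# 3 drugs (1-3), 3 diseases (4-6), 5 genes (7-11).
toyGraph <- function() {
  reg <- nodeRegistry()
  reg <- addNodes(reg, c("r1", "r2", "r3"), "drug")
  reg <- addNodes(reg, c("d1", "d2", "d3"), "disease")
  reg <- addNodes(reg, c("g1", "g2", "g3", "g4", "g5"), "gene")
  buildHeteroGraph(reg, list(
    "drug-disease" = cbind(c(1L, 1L, 2L), c(4L, 5L, 5L)),
    "drug-gene"    = cbind(c(1L, 2L, 3L), c(7L, 7L, 8L)),
    "disease-gene" = cbind(c(4L, 5L), c(9L, 7L)),
    "gene-gene"    = cbind(c(7L, 8L, 9L), c(8L, 9L, 10L))))
}

# Chain: anchor(1, drug) - g(3) - g(4) - g(5) - g(6) - g(7); one disease(2)
# kept isolated so the graph stays well-typed.
chainGraph <- function() {
  reg <- nodeRegistry()
  reg <- addNodes(reg, "r1", "drug")
  reg <- addNodes(reg, "d1", "disease")
  reg <- addNodes(reg, paste0("g", 1:5), "gene")
  buildHeteroGraph(reg, list(
    "drug-gene" = cbind(1L, 3L),
    "gene-gene" = cbind(3:6, 4:7)))
}

# Star: anchor(1) attached to 5 genes with no gene-gene edges.
starGraph <- function() {
  reg <- nodeRegistry()
  reg <- addNodes(reg, "r1", "drug")
  reg <- addNodes(reg, "d1", "disease")
  reg <- addNodes(reg, paste0("g", 1:5), "gene")
  buildHeteroGraph(reg, list("drug-gene" = cbind(1L, 3:7)))
}

writeTempEdgeList <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
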