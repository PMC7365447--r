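extdata <- function(name) {
  path <- system.file("extdata", name, package = "pbfit")
  if (path == "") path <- file.path("..", "..", "inst", "extdata", name)
  path
}

table3_cohort <- function() read_cohort(extdata("table3.csv"))
table2_cohort <- function() read_cohort(extdata("table2_partial.csv"))

# candidate_features object built directly from a matrix, for unit tests of
# the selection machinery on hand-made columns
make_cf <- function(values, target = NULL, distance_features = colnames(values)) {
  structure(list(values = values, feature_names = colnames(values),
                 target = target, distance_features = distance_features),
            class = "candidate_features")
}

# hand-made feature_weights object
make_weights <- function(features, weights) {
  structure(data.frame(feature = features, weight = weights,
                       check.names = FALSE),
            class = c("feature_weights", "data.frame"))
}

# small evaluated population with distinct genes
make_population <- function(M, fitness, n_genes = 3, scale = 1000) {
  genes <- matrix(seq_len(M * n_genes) * scale, nrow = M)
  structure(list(genes = genes, fitness = fitness, generation = 1L),
            class = "pbf_population")
}
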