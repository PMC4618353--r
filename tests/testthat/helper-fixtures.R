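# shared fixtures and independent oracles

toy_annotation <- function(ids, muller, neo_x = "pse") {
  gene_annotation(ids, muller, neo_x_species = neo_x)
}

quartet_tree <- function(text = "((mel:1,yak:1):0.5,(pse:1,vir:1):0.5);") {
  check_tree(ape::read.tree(text = text), c("mel", "yak", "pse", "vir"))
}

# numeric REML oracle for the Brownian-motion rate: maximizes the restricted
# likelihood written in matrix form (GLS mean profiled out), independent of
# the contrasts recursion used by the implementation
reml_sigma2_oracle <- function(tip_values, tree) {
  C <- ape::vcv(tree)[names(tip_values), names(tip_values)]
  Ci <- solve(C)
  one <- rep(1, length(tip_values))
  mu <- as.numeric((one %*% Ci %*% tip_values) / (one %*% Ci %*% one))
  e <- tip_values - mu
  q <- as.numeric(e %*% Ci %*% e)
  nl <- function(s2) {
    n <- length(tip_values)
    0.5 * ((n - 1) * log(2 * pi * s2) + log(det(C)) +
           log(sum(Ci)) + q / s2)
  }
  stats::optimize(nl, c(1e-10, max(q, 1e-6) * 10), tol = 1e-12)$minimum
}

# classified sex-bias table stub for cross-species set tests
bias_table_stub <- function(ids, class, rank) {
  data.frame(orthogroup_id = ids, species = "x", log2_ratio = NA_real_,
             evaluated = class != "not_evaluated",
             quantile_rank = rank, bias_class = class,
             stringsAsFactors = FALSE)
}
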