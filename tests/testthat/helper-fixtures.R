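# Shared builders for unit tests. All fixtures are constructed in code.

# one-row trio variant record with clean defaults; override any field
trio_record <- function(chrom = "1", pos = 1000L, ref = "A", alt = "G",
                        gt_proband = "0/1", gt_father = "0/0",
                        gt_mother = "0/0",
                        gq_proband = 60, gq_father = 60, gq_mother = 60,
                        dp_proband = 40, dp_father = 40, dp_mother = 40,
                        alt_proband = 20, alt_father = 0, alt_mother = 0,
                        proband_sex = "male",
                        gene = "GENE1", cadd = 25, af = 1e-4,
                        impact = "MODERATE") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gt_proband = gt_proband, gt_father = gt_father,
             gt_mother = gt_mother, gq_proband = gq_proband,
             gq_father = gq_father, gq_mother = gq_mother,
             dp_proband = dp_proband, dp_father = dp_father,
             dp_mother = dp_mother, alt_proband = alt_proband,
             alt_father = alt_father, alt_mother = alt_mother,
             proband_sex = proband_sex, gene = gene, cadd = cadd, af = af,
             impact = impact, stringsAsFactors = FALSE)
}

diploid_gts <- c("0/0", "0/1", "1/1")
hemi_gts <- c("0", "1")

# independent truth tables for the trio patterns, written directly from the
# Mendelian definitions (not via the package predicates)
oracle_de_novo <- function(p, f, m) {
  f == "0/0" && m == "0/0" && p == "0/1"
}
oracle_ar <- function(p, f, m) {
  p == "1/1" && f == "0/1" && m == "0/1"
}
oracle_xlr_male <- function(p, f, m) {
  p == "1" && f == "0" && m == "0/1"
}

# independent connectivity check used as the oracle for connector searches:
# reachability by repeated neighbor expansion over an adjacency matrix
oracle_connected <- function(adj, vids) {
  if (length(vids) <= 1) return(TRUE)
  sub <- adj[vids, vids, drop = FALSE]
  reached <- c(vids[1])
  repeat {
    nxt <- unique(c(reached,
                    vids[colSums(sub[reached, , drop = FALSE]) > 0]))
    if (length(nxt) == length(reached)) break
    reached <- nxt
  }
  length(reached) == length(vids)
}

# exhaustive minimal-connector oracle over all candidate subsets
oracle_min_connectors <- function(adj, seeds, candidates, k_max) {
  for (k in 0:min(k_max, length(candidates))) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(candidates, k, simplify = FALSE)
    hits <- Filter(function(s) oracle_connected(adj, c(seeds, s)), subsets)
    if (length(hits)) return(list(k = k, sets = hits))
  }
  list(k = NA_integer_, sets = list())
}

adjacency_from_edges <- function(edges, nodes) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$a[i], edges$b[i]] <- TRUE
    adj[edges$b[i], edges$a[i]] <- TRUE
  }
  adj
}

# random typed edge list over n nodes
random_edges <- function(n, p, prefix = "V") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  list(nodes = nodes,
       edges = data.frame(a = pairs[1, keep], b = pairs[2, keep],
                          channel = rep("experimental_ppi", sum(keep)),
                          stringsAsFactors = FALSE))
}
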