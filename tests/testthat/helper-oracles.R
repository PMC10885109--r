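# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Position-wise identity by explicit character comparison.
ref_identity <- function(a, b) {
  ca <- substring(a, seq_len(nchar(a)), seq_len(nchar(a)))
  cb <- substring(b, seq_len(nchar(b)), seq_len(nchar(b)))
  mean(ca == cb)
}

# Naive greedy incremental clustering of one (gene, length) block: sequences
# ordered by descending multiplicity then lexicographically; each joins the
# first cluster whose founding representative it matches at >= thr.
ref_greedy <- function(seqs, thr) {
  tab <- sort(table(seqs), decreasing = TRUE)
  ord <- names(tab)[order(-as.integer(tab), names(tab))]
  reps <- character(0)
  assign <- integer(0)
  out <- setNames(integer(length(ord)), ord)
  for (s in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (ref_identity(s, reps[k]) >= thr) {
        out[s] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      out[s] <- length(reps)
    }
  }
  out[seqs]
}

# Partition equality up to relabeling: same co-clustering relation.
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# Brute-force Gini by the pairwise-difference definition.
ref_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Exact two-sided rank-sum p-value by enumerating all assignments of the
# pooled ranks to group x.
ref_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  splits <- utils::combn(length(pooled), nx)
  ws <- apply(splits, 2, function(idx) sum(r[idx]))
  ex <- mean(ws)
  mean(abs(ws - ex) >= abs(obs - ex) - 1e-12)
}

# Build a toy rearrangement record table.
toy_records <- function(cell_id, locus, productive = TRUE,
                        v_call = "IGHV1-1", cdr3 = "CARW") {
  n <- length(cell_id)
  data.frame(
    cell_id = cell_id,
    sequence_id = sprintf("seq%03d", seq_len(n)),
    locus = locus,
    v_call = rep_len(v_call, n),
    j_call = "IGHJ2",
    c_call = "IGHG1",
    productive = rep_len(productive, n),
    cdr1_aa = "GYTFTSYW",
    cdr2_aa = "IDPNSGGT",
    cdr3_aa = rep_len(cdr3, n),
    sequence_aa = "EVQLQQ",
    sequence = "GAAGTT",
    stringsAsFactors = FALSE
  )
}

# Synthetic atom table: one carbon sphere per residue placed on a loose
# helix so neighboring residues partially occlude each other.
helix_atoms <- function(n, chain = "L", spacing = 3.8, radius_per_turn = 5) {
  t <- seq_len(n)
  data.frame(
    chain = chain,
    resno = t,
    resid = "ALA",
    elety = "CA",
    element = "C",
    x = radius_per_turn * cos(t * 0.6),
    y = radius_per_turn * sin(t * 0.6),
    z = t * spacing / 2,
    stringsAsFactors = FALSE
  )
}

# Analytic accessible area of a sphere of radius r1 occluded by one sphere
# of radius r2 at center distance d (spherical cap removal).
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  cos_theta <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  h <- r1 * (1 - cos_theta)
  4 * pi * r1^2 - 2 * pi * r1 * h
}
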