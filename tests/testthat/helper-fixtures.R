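# Shared fixtures: all generated in code, no binary files.

# Random lysine-rich protein sequence (tryptic-peptide friendly).
random_protein <- function(n, seed) {
  withr::with_seed(seed, {
    alphabet <- c(strsplit("ACDEFGHILMNPQSTVWY", "")[[1]],
                  rep("K", 4), rep("R", 2))
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
  })
}

# Receptor fixture carrying the four catalytic-domain anchors of interest:
# the two tail lysines 61.3 A apart and the internal-control pair at 11.2 A.
# Distances are derived from explicit 3-D points so the matrix is realizable.
receptor_fixture <- function() {
  pts <- rbind(c(0, 0, 0), c(61.3, 0, 0), c(20, 15, 0), c(25.6, 15, 9.7))
  dm <- as.matrix(stats::dist(pts))
  # pin the control pair at exactly 11.2 A by nudging the last point
  u <- (pts[4, ] - pts[3, ]) / sqrt(sum((pts[4, ] - pts[3, ])^2))
  pts[4, ] <- pts[3, ] + 11.2 * u
  dm <- as.matrix(stats::dist(pts))
  make_structure_fixture(
    data.frame(chain = c("A", "B", "A", "B"),
               resno = c(672L, 615L, 606L, 559L)), dm)
}

# Target db from two synthetic proteins plus reversed decoys, indexed pairs
# planted from its target peptides.
planted_search_world <- function(n_pairs = 10L, seed = 2L) {
  targets <- c(protX = random_protein(120, 11), protY = random_protein(120, 12))
  db <- build_database(targets, params = digest_params())
  idx <- index_peptides(db)
  tgt <- idx[!idx$is_decoy, ]
  pairs <- withr::with_seed(seed, {
    pick <- sample(nrow(tgt), 2L * n_pairs)
    lapply(seq_len(n_pairs), function(k) {
      i <- pick[2 * k - 1]; j <- pick[2 * k]
      pepA <- with_cam(peptide(tgt$sequence[i], protein = tgt$protein[i],
                               start = tgt$start[i], end = tgt$end[i]))
      pepB <- with_cam(peptide(tgt$sequence[j], protein = tgt$protein[j],
                               start = tgt$start[j], end = tgt$end[j]))
      xl_pair(pepA, pepB, tgt$sites[[i]][1], tgt$sites[[j]][1])
    })
  })
  list(db = db, pairs = pairs)
}

# Independent brute-force digestion oracle: every substring that starts and
# ends at a cleavage boundary with at most max_missed internal boundaries.
digest_oracle <- function(sequence, max_missed, min_len = 1L,
                          max_len = nchar(sequence)) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  sites <- which(vapply(seq_len(n), function(i)
    aa[i] %in% c("K", "R") && (i == n || aa[i + 1] != "P"), NA))
  starts <- unique(c(1L, sites + 1L)); starts <- starts[starts <= n]
  ends <- unique(c(sites, n))
  out <- character(0)
  for (s in starts) for (e in ends) {
    if (e < s) next
    if (sum(sites >= s & sites < e) > max_missed) next
    len <- e - s + 1L
    if (len < min_len || len > max_len) next
    out <- c(out, substr(sequence, s, e))
  }
  sort(unique(out))
}

# Count of correctly re-identified planted pairs in a PSM table, allowing
# either chain order.
n_recovered <- function(psms, truth) {
  ok <- merge(psms, truth, by = "spectrum_id")
  sum((ok$pepA.x == ok$pepA.y & ok$pepB.x == ok$pepB.y &
         ok$posA.x == ok$posA.y & ok$posB.x == ok$posB.y) |
        (ok$pepA.x == ok$pepB.y & ok$pepB.x == ok$pepA.y &
           ok$posA.x == ok$posB.y & ok$posB.x == ok$posA.y))
}

# Random rigid rotation matrix.
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
             2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
             2 * (b * d - a * c), 2 * (c * d + a * b),
             a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
  })
}
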