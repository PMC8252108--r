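# Deterministic fixture builders (no RNG).

# minimal long table: `ids` samples x 13 measured AAs x elements, values with
# two decimals so CSV round-trips are exact
make_fixture_table <- function(ids = c("h1", "h2"),
                               fractions = rep("host", length(ids)),
                               elements = c("C", "N")) {
  aa <- aa_set("measured13")
  rows <- expand.grid(sample_id = ids, amino_acid = aa, element = elements,
                      stringsAsFactors = FALSE)
  attr(rows, "out.attrs") <- NULL
  rows$fraction <- fractions[match(rows$sample_id, ids)]
  rows$treatment <- "L-NF"
  base <- seq(-20, -8, length.out = length(aa))
  rows$delta <- round(base[match(rows$amino_acid, aa)] +
                        2 * (match(rows$sample_id, ids) - 1) +
                        ifelse(rows$element == "N", 25, 0), 2)
  rows$sd <- 0.25
  rows$n_rep <- 3
  aa_isotope_table(rows)
}

# two well-separated Gaussian classes in `p` dimensions
make_two_class <- function(n = 20, p = 4, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p, 0, sd), n, p),
             matrix(rnorm(n * p, sep, sd), n, p))
  colnames(x) <- paste0("V", seq_len(p))
  list(x = x, labels = rep(c("a", "b"), each = n))
}

# is a 2D point inside an ellipse_params ellipse?
point_in_ellipse <- function(pts, ell) {
  rot <- matrix(c(cos(ell$angle), sin(ell$angle),
                  -sin(ell$angle), cos(ell$angle)), 2, 2)
  z <- sweep(as.matrix(pts), 2, ell$center) %*% rot
  (z[, 1] / ell$semi_axes[1])^2 + (z[, 2] / ell$semi_axes[2])^2 <= 1
}
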