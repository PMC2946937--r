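# Shared fixtures: toy Newick trees and generators built in code.

toy3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
toy4 <- function() ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")

# Yule internode intervals: while j lineages exist the waiting time is
# Exp(j * lambda), j = 2..n (g_n is the terminal interval).  Returns a
# coalescent_times object with the exact Yule node-depth distribution.
yule_times <- function(n, lambda = 1) {
  g <- stats::rexp(n - 1, rate = seq.int(2L, n) * lambda)
  depths <- rev(cumsum(rev(g)))   # t_{n-1}, ..., t_1 summed tip-ward
  as_coalescent_times(depths)
}

# random ultrametric tree (standard coalescent shape, arbitrary scale)
random_ultrametric <- function(n) ape::rcoal(n)

expect_equal_ct <- function(a, b, tol = 1e-6) {
  expect_equal(a$n, b$n)
  expect_equal(a$node_depths, b$node_depths, tolerance = tol)
  expect_equal(a$terminal, b$terminal, tolerance = tol)
}
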