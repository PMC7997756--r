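# Shared fixtures: all images are generated in code, nothing on disk.

test_key <- function(x0 = c(0.31, 0.62, 0.47)) chaos_key(x0 = x0)

rand_img <- function(p, q = p, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:255, p * q, replace = TRUE), p, q)
}

# chi-square statistic of a 256-bin pixel histogram against uniform
hist_chisq <- function(img) {
  cnt <- tabulate(as.vector(img) + 1L, 256L)
  e <- length(img) / 256
  sum((cnt - e)^2 / e)
}
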