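# medimcrypt

Privacy-preserving handling and automated diagnosis of 8-bit grayscale
medical images, in R. Medical images routinely leave the machine that
acquired them — for cloud storage, for remote reading, for research — and
both requirements of that journey are covered here: a **chaotic image
cipher** so the stored image leaks nothing, and a **diagnosis stack**
(principal-component reduction, K-means segmentation, a fuzzy
convolutional classifier) that runs on the faithfully decrypted images.
Seeded synthetic brain phantoms make every stage testable offline, with
no external data.

## The algorithms

**Cipher.** A confusion–diffusion stream cipher keyed by a
three-component chaotic system (three logistic maps
x ← r·x·(1−x), r ∈ {3.99, 3.98, 3.97}, behind a pluggable interface):

* *Keystream* — iterate the system `transient + n` times, discard the
  transient, quantize each value u to the byte ⌊u·10¹⁰⌋ mod 256, and
  form R₁ = b₁⊕b₂, R₂ = b₂⊕b₃.
* *Confusion* — an extended zigzag scan (anti-diagonal boustrophedon,
  valid for any rectangle) whose start corner is chosen by a reserved
  chaotic draw, ⌊v·10⁴⌋ mod 4.
* *Diffusion* — two rounds of a forward pass with R₁ and a reverse pass
  with R₂ of the carry-propagating chain
  Eᵢ = Qᵢ ⊕ rotl₈((Rᵢ + Eᵢ₋₁) mod 256, 3).
  (The plain XOR chain Eᵢ = Eᵢ₋₁⊕Rᵢ⊕Qᵢ is also provided, but being
  affine over GF(2) it cannot produce full avalanche — see the methods
  vignette.)
* Optional block-autoencoder compression (tansig hidden layer, logsig
  output, rate t = uᵢ/uₜ) before confusion; the default mode is
  bit-lossless, which is what a downstream classifier needs.

**Cryptanalysis metrics.** Shannon entropy of the pixel histogram
(ideal: 8 bits), adjacent-pixel correlation over 2000 seeded neighbour
pairs in three directions, and the differential-attack pair

* NPCR = 100 · #{E₁(i,j) ≠ E₂(i,j)} / (m·n), expectation
  100·(1−2⁻⁸) = 99.61 for a strong cipher,
* UACI = 100 · mean |E₁−E₂| / 255, expectation 33.46.

**Diagnosis.** `fit_ipca()` selects principal components by cumulative
explained variance (strict > 85% by default); `segment_image()` runs
seeded Lloyd iterations with a per-iteration objective trace;
`fcnn_model()`/`fcnn_train()` implement a fuzzy convolutional network —
Gaussian fuzzification of the input, convolution with fuzzified kernels,
ReLU + max pooling, centre-of-gravity defuzzification, sigmoid output —
trained by full-batch gradient descent on cross-entropy, with analytic
gradients for every parameter group.

## Worked example

```r
library(medimcrypt)

key <- chaos_key(x0 = c(0.2461, 0.3582, 0.7913))   # the secret
ph  <- generate_phantom(phantom_config(), seed = 7, force_tumour = TRUE)

enc <- encrypt_image(ph$image, key)
dec <- decrypt_image(enc, key)
identical(dec, ph$image)
#> [1] TRUE

security_report(ph$image, key, n_pairs = 2000, seed = 7)
#> <security_report>
#>   entropy   plain 5.9324  cipher 7.9550 bits
#>   corr plain   H +0.9135  V +0.9132  D +0.8926
#>   corr cipher  H +0.0000  V +0.0076  D +0.0129
#>   NPCR 99.4385 %   UACI 32.9259 %  (2000 pairs, seed 7)

seg <- segment_image(ph$image, k = 3, seed = 1)
mean(seg$labels[ph$mask] == 3)   # tumour pixels in the brightest class
#> [1] 1
```

Reading the report: the plain phantom has strongly correlated neighbours
(≈0.9) and low entropy; its ciphertext is indistinguishable from noise —
entropy near 8 bits (7.955 is the unbiased expectation for a 64×64
image), correlations near zero, and a one-pixel change in the plaintext
changes 99.4% of ciphertext pixels with a mean intensity shift of ≈33%,
the theoretical values for an ideal 8-bit cipher at this image size.

A full simulate → encrypt → verify-round-trip → segment → train →
evaluate run is one call:

```r
run_pipeline(pipeline_config(n_images = 50, seed = 7))
#> <pipeline_report> seed 7 | 50 phantoms
#>   cipher: entropy 7.8228, NPCR 99.32%, UACI 33.82%
#>   classifier: accuracy 1.000, sensitivity 1.000, specificity 1.000 (n_test 12)
```

A thin command-line front end over the same functions lives at
`inst/cli/medimcrypt.R` (subcommands `keygen`, `simulate`, `encrypt`,
`decrypt`, `analyze`, `segment`, `pipeline`).

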