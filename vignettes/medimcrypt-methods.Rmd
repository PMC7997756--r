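---
title: "Methods: chaotic image encryption and fuzzy convolutional diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaotic image encryption and fuzzy convolutional diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

medimcrypt is a toolkit for privacy-preserving handling of 8-bit grayscale
medical images: images are encrypted before leaving the acquisition site,
decrypted where diagnosis happens, and classified as normal or abnormal by
a fuzzy convolutional network, with principal-component reduction and
K-means segmentation available as preprocessing. This vignette documents
the models, the parameters that matter, the numerical decisions, and what
the synthetic phantoms do and do not establish.

```{r setup}
library(medimcrypt)
```

## The keystream: three logistic maps behind a pluggable interface

The cipher is keyed by the initial state and control parameters of a
three-component chaotic system. The implemented system, `"logistic3"`, is
three independent logistic maps

$$x_{t+1} = r\,x_t(1 - x_t), \qquad r \in \{3.99, 3.98, 3.97\},$$

all in the fully chaotic regime. Chaotic ciphers in the literature use
many different systems, including fractional-order ones; the `system`
field of `chaos_key()` is an enum precisely so another system can be
plugged in without touching the rest of the cipher. The logistic map was
chosen as the default because it is the canonical one-line recurrence of
this literature, trivially testable against a hand-computed orbit.

Key points of the construction:

* **Transient.** The first `transient` iterates (default 1000) are
  discarded. This deepens sensitivity to every digit of the key: after a
  thousand chaotic steps, a `1e-10` perturbation of one initial value
  decorrelates the orbit completely (the package asserts at least 95% of
  keystream bytes change; in practice about 99.6% do).
* **Quantization.** A raw value $u \in (0,1)$ becomes the byte
  $\lfloor u \cdot 10^{10}\rfloor \bmod 256$. The scale $10^{10}$ reaches
  far below the map's invariant-density structure, so bytes are nearly
  uniform; the product stays below $2^{53}$ and is therefore exact in
  double precision, which makes keystreams bit-reproducible across
  platforms.
* **Combination.** With the three quantized streams $b_1, b_2, b_3$, the
  diffusion keystreams are $R_1 = b_1 \oplus b_2$ and
  $R_2 = b_2 \oplus b_3$. XOR-ing two quantized streams flattens any
  residual non-uniformity and ties each output byte to two chaotic
  components.
* **Reserved draws.** The first post-transient value is reserved for
  choosing the confusion corner, *before* any diffusion byte is drawn, so
  the corner choice and the keystream are independent. The boundary bytes
  of the two diffusion chains are quantized from the *last discarded*
  values of components 1 and 3 — still key material, never transmitted.

## Confusion: the extended zigzag scan

The confusion stage permutes pixel positions. The scan visits
anti-diagonals $d = i + j$ in increasing order, alternating direction
(down-left on odd diagonals, up-right on even ones) — at the top-left
corner this is exactly the classic JPEG zigzag. The other three corners
are the horizontal/vertical reflections of that traversal, and the
construction is well defined for any rectangular matrix. Which corner is
used is decided by the reserved chaotic draw,
$\lfloor v\cdot 10^4\rfloor \bmod 4$, so the permutation itself is key
material. The scanned sequence is rewritten into the grid row-major;
`unscramble()` inverts the permutation exactly.

## Diffusion: why the chain is ARX and why there are two rounds

The diffusion stage chains every ciphertext byte to its predecessor, the
keystream and the current plaintext byte, in a forward pass with $R_1$
followed by a reverse pass with $R_2$. Two chaining rules are
implemented.

The plain XOR chain, $E_i = E_{i-1} \oplus R_i \oplus Q_i$, is provided
as `op = "xor"` and is useful didactically, but it cannot carry a
differential benchmark: XOR is linear over $\mathrm{GF}(2)$, so any
composition of permutations and XOR chains is an *affine* map of the
plaintext. The ciphertext difference produced by a one-pixel change is
then a fixed pattern — the difference telescopes along the chain and
cancels pairwise — and no number of passes can push the changed fraction
to the $1 - 2^{-8} \approx 99.6\%$ that a diffusion benchmark demands
(measured, the two-pass XOR chain changes roughly half the bytes, and
every byte-level difference equals the injected one). A carry-propagating
step is mathematically required, and a plain modular addition is not
enough either: $(x + 128) \bmod 256 = x \oplus 128$, so a difference
confined to the top bit propagates linearly again (an absorbing state we
observed dragging single trials down to 34%). The cipher therefore uses a
standard ARX (add–rotate–xor) step,

$$E_i = Q_i \oplus \mathrm{rotl}_8\big((R_i + E_{i-1}) \bmod 256,\ 3\big),$$

in which the addition propagates carries upward and the 3-bit rotation
moves the top bit down so no fixed bit position is absorbing. Inversion
needs no inverse of the mixing function because it only consumes
already-known ciphertext bytes: $P_i = C_i \oplus
\mathrm{rotl}_8((S_i + C_{i-1}) \bmod 256, 3)$.

**Two rounds.** With a single forward+reverse round there remains a
$2^{-8}$-probability event per encryption: if the chain value at the
modified position happens to coincide between the two ciphertexts during
the reverse pass, the entire prefix below it stays unchanged, producing a
heavy left tail in per-trial NPCR (means around 99.48 instead of 99.61).
The default is therefore two rounds, each consuming *fresh* keystream
bytes (reusing a keystream across rounds re-introduces structured
cancellations). With two rounds the one-pixel differential behaves like a
pair of independent uniform images: NPCR concentrates at
$100(1 - 2^{-8}) = 99.6094$ and UACI at
$100 \cdot \frac{256^2 - 1}{3 \cdot 256 \cdot 255} = 33.4635$.

```{r differential, eval = FALSE}
differential_analysis(n_trials = 50, size = 256, seed = 1)[c("mean_npcr",
                                                             "mean_uaci")]
#> $mean_npcr  99.6124
#> $mean_uaci  33.4567
```

## Lossless by default; compression as an option

Decrypted images feed a diagnostic classifier, so the default pipeline is
bit-lossless: the cipher operates directly on the raw 8-bit pixels and
`decrypt_image(encrypt_image(img, key), key)` is the exact identity for
any shape down to 1×1. The optional compression mode inserts, before
confusion, a min–max normalization to $[0,1]$ followed by a block
autoencoder: blocks of `block_size`² pixels (reflect-padded to fit, the
padding recorded and stripped on reassembly) are encoded to
`hidden_nodes` tansig activations — the compression rate is
$t = u_i/u_t$ — quantized to 8 bits, and that $H \times u_t$ code image is
what gets scrambled and diffused. The autoencoder (tansig hidden, logsig
output) is trained on the image's own blocks by full-batch gradient
descent with momentum, seeded and reproducible. This path is lossy by
construction (quantization plus a learned decoder); on smooth images the
default settings reach PSNR above 25 dB. Two documented limitations: the
decoder weights travel in the metadata sidecar in cleartext, and there is
no integrity tag — decryption under a wrong key silently yields noise.

The printed min–max normalization and the UACI normalizer in this
literature are frequently garbled; here normalization is the standard
$(x - X_{\min})/(X_{\max} - X_{\min})$ map onto the target interval
(constant images map to the lower target bound), and UACI divides by 255,
the only choice whose expectation matches the 33.46% benchmark for 8-bit
images.

## Cryptanalysis metrics

* **Entropy.** Shannon entropy of the 256-bin histogram; 8 bits is
  ideal. A 512×512 ciphertext reaches about 7.9993 — the small deficit is
  the expected plug-in estimator bias $(K-1)/(2N\ln 2)$, not a cipher
  weakness.
* **Adjacent-pixel correlation.** Pearson correlation over `n_pairs`
  (default 2000, seeded, without replacement) random pairs of neighbours;
  `"diagonal"` means offset $(+1,+1)$. A constant marginal makes the
  coefficient undefined; the function returns 0 flagged
  `degenerate = TRUE` rather than dividing by zero.
* **NPCR / UACI.** Fraction of differing positions, and mean absolute
  difference over 255, both as percentages. `security_report()` composes
  all metrics for a plain image: it encrypts the image and a copy with
  one random pixel replaced, and fills every field deterministically
  under its seed.

## Principal components with explained-variance selection

`fit_ipca()` centres columns, forms the $\tfrac1n$-scaled covariance,
eigendecomposes, sorts eigenvalues descending and keeps the smallest
number of components whose cumulative contribution rate *strictly
exceeds* the threshold (default 85%). Numerical decisions: eigenvalues
are clamped at zero (symmetric eigensolvers can return $-10^{-16}$);
eigenvector signs are fixed so each column's largest-magnitude entry is
positive, making fits reproducible; zero-variance data is an error rather
than a silent degenerate fit. With all components retained, the
reconstruction error is at round-off level (orthonormal basis), which the
tests bound at $10^{-8}$ relative Frobenius norm.

## K-means segmentation

`kmeans_lloyd()` is a deliberate re-implementation of Lloyd iterations
rather than a call to `stats::kmeans`, because the surface exposes
behaviour the packaged version does not: the objective value after every
assignment step (the within-cluster sum of squares — the quantity the
iterations actually minimize), lowest-index tie-breaking in assignment,
and re-seeding of an emptied centre at the point farthest from its
nearest centre. `stats::kmeans` with `algorithm = "Lloyd"` and identical
initial centres serves as the independent cross-check in the test suite,
converging to the same objective. `segment_image()` clusters pixel
intensities and relabels clusters by ascending centre so "label k" is
always the brightest tissue class — on tumour phantoms the tumour mask
lands in the top label.

## The fuzzy convolutional network

The classifier composes, per image (intensities scaled to $[0,1]$):

1. **Fuzzification.** Gaussian memberships
   $\hat X_f = \exp(-(X - Mx_f)^2 / 2\sigma_f^2)$ for each of `n_mf`
   (default 2) membership functions.
2. **Fuzzy convolution.** Each kernel's weights first pass through their
   own Gaussian membership (centre $Mz_c$, width $\sigma_z$); the
   fuzzified kernel is then convolved (valid, no padding) with every
   membership grid. `conv_mode = "sum"` is the ordinary sum of products;
   `"minmax"` replaces multiply/add with min/max (the fuzzy relational
   composition). Sum is the default and the only mode with full
   gradients; in minmax mode the kernel path is frozen and only the
   output layer and defuzzification centres train.
3. **ReLU + max pooling** over a fixed `pool_grid` of contiguous windows
   (default 2×2). A *grid* of windows, not one global maximum, is
   essential: the next stage normalizes away overall magnitude, so with
   a single window every image would collapse to nearly the same
   feature.
4. **Defuzzification.** Centre of gravity across the membership
   branches, per kernel and window:
   $y_{c,w} = \sum_f My_{f,c}\, p_{f,c,w} \big/ \sum_f p_{f,c,w}$ — a
   convex combination of the $My$ centres; an all-zero window falls back
   to their mean.
5. **Output.** A fully connected sigmoid unit,
   $\hat z = \sigma(\sum W\!f_{c,w}\, y_{c,w} + b)$, for the binary
   normal/abnormal decision.

**Where the membership centres go.** Because centre-of-gravity
defuzzification is scale-invariant, the feature a window produces is
essentially "which membership centre is this window's intensity closer
to". Class information survives only if the two centres *bracket* the
intensities that distinguish the classes. Centres placed at interior
quantiles both land on the dominant tissue mode and a bright lesion
becomes invisible in the membership ratio. `fcnn_train()` therefore
calibrates the centres at the 1st and 99th percentiles of the training
pixel intensities — linguistic "dark" and "bright" — with widths set to
half the centre distance. This is the single most consequential design
choice in the classifier.

**Training.** Full-batch gradient descent on the clipped binary
cross-entropy ($\varepsilon = 10^{-12}$, natural log), with per-group
learning rates (defaults: output weights 0.5, defuzzification centres
0.05, kernel and input membership centres 0.02). All updates are descent
steps $\theta \leftarrow \theta - \delta\,\partial CE/\partial\theta$;
the gradients are derived by the chain rule through the sum-mode network
(through the pooled argmax and the active ReLU branch) and every
parameter group is verified against central finite differences to a
relative error below $10^{-4}$ in the tests. Max-pool and ReLU make the
loss piecewise smooth; the checks are run at generic points away from
ties. Learning with shuffled labels collapses to chance, which the suite
verifies with a joint label permutation.

## Synthetic phantoms: what they are and what they show

`generate_phantom()` draws an ellipse ("brain", default intensity 90) on
a dark background (15) with Gaussian noise ($\sigma = 8$), and with
configurable probability a bright disk ("tumour", brain + 110, radius
4–8 px at the default 64×64). Everything is driven by one seed;
`generate_dataset()` stratifies classes exactly and gives every phantom
its own sub-seed. The defaults put the tumour contrast at nearly 14
noise standard deviations — a cleanly separable problem by design, since
the classifier acceptance is parameter/label recovery, not clinical
validity.

What the phantoms deliberately do **not** model: anatomy (no tissue
layers, no ventricles), partial-volume effects at boundaries, bias
fields, speckle or Rician noise statistics, and lesion texture. Passing
tests therefore establish that the implementation is correct and that
the pipeline recovers known structure under its stated conditions; they
say nothing about accuracy on clinical MRI.

## Problem sizes and runtime choices

The test suite and the acceptance script use sizes chosen to exercise
the mathematics at full fidelity while staying desk-scale: differential
benchmarks run 50 trials on 256×256 uniform plaintexts (the keystream
recurrences and diffusion chains are compiled, so this takes seconds);
entropy checks use 512×512 images over 10 keys; classifier benchmarks
train on 60 and test on 20 phantoms of 32×32 pixels for 50 epochs, with
a 75/25 split throughout. Eigen-spectrum and clustering checks use
$10^3$–$10^4$ samples, where sampling error is far below the asserted
tolerances.

## Known limitations

* The chaotic system is a stand-in: the interface accepts other systems,
  but only `logistic3` ships.
* No authentication: ciphertext tampering or a wrong key yields noise,
  never an error.
* Compression mode protects the pixel stream but not the decoder
  weights in the sidecar.
* The classifier is binary with a single sigmoid unit; multiclass output
  is out of scope.
* Min/max composition mode trains only part of the model
  (subgradients through min/max kernels are not propagated).
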