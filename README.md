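# patternfit

Data-driven analysis of biological pattern formation from steady-state
snapshot images, in two parts:

1. **Model selection.** Which pattern-forming mathematical models could
   have produced a target image?  A library of simulated patterns (Turing
   reaction–diffusion, kernel-based Turing, Gray–Scott, Edwards–Wilkinson,
   Eden, diffusion-limited aggregation, L-systems, phase-field growth) is
   embedded into a shared 512-dimensional latent space; candidates are
   retrieved by cosine similarity, with a centre-crop scan over the target
   to absorb scale mismatch, and cross-model retrieval structure is
   quantified by MAP@k matrices.
2. **Parameter estimation (SD-NPE).** For the two-species Turing model

   ∂u/∂t = f_u u − f_v v + q u² − u³ + D_u ∇²u,
   ∂v/∂t = g_u u − g_v v + D_v ∇²v,

   *Simulation-Decoupled Neural Posterior Estimation* infers the posterior
   of (f_v, g_v) from a handful of images: a probabilistic boosting
   regressor (natural-gradient boosting with a bivariate-normal head)
   predicts a per-image posterior from 2-d features learned by modified
   contrastive metric learning, and an arbitrary number of per-image
   posteriors are combined on a 100×100 parameter lattice via

   log p(w | x₁..x_N) = Σᵢ log p(w | xᵢ) − (N−1) log p̂(w) + const,

   where the prior p̂ is the pixel-wise average of the per-sample
   posteriors over the training set.  Training is fully decoupled from
   inference: no new simulations are needed at estimation time.

Closed-form Turing linear-stability analytics — the dispersion relation,
the fastest-growing wavenumber k_max and the unstable-band feature
D_k = ln(k_right²/k_left²) — serve as independent oracles throughout, and
the conjugate normal linear-regression model provides an exact analytic
benchmark for the SD-NPE machinery.

Everything runs offline: the simulator suite doubles as the data
generator, and a deterministic spectral image encoder stands in for the
zero-shot CLIP ViT-B/32 adapter (which can be plugged in where its weights
are available, and errors loudly when they are not).

## Worked example

Simulate a Turing pattern, check its spatial scale against the analytic
prediction, and estimate its parameters from 20 snapshots:

```r
library(patternfit)

p <- turing_params(f_v = 0.9078, g_v = 0.8018)
u <- simulate_turing(p, size = 48, dt = 0.2, steps = 2000, seed = 3)

kmax_closed(p)            # 1.362613   analytic fastest-growing wavenumber
dominant_wavenumber(u)    # 1.439897   dominant wavenumber of the image
dk_closed(p)              # 1.212746   log unstable-band width

# full estimation pipeline on a scaled-down dataset (~10 min)
bundle <- build_estimation_bundle(n_train = 2000, n_val = 300, size = 48,
                                  seed = 1, blur_sigma = 0.75)
model <- fit_sdnpe(bundle, tspec = train_spec(seed = 1), seed = 1)

imgs <- lapply(1:20, function(i)
  normalize_field(simulate_turing(p, size = 48, dt = 0.2, steps = 2000,
                                  seed = 100 + i)))
post <- estimate_parameters(model, imgs)
hpd_contains(post, c(0.9078, 0.8018), level = 0.95)   # TRUE
```

The first three numbers say: the linear theory predicts stripes at
wavenumber 1.36 radians/pixel (wavelength ≈ 4.6 px), the simulated image's
radial power spectrum peaks at 1.44 (within 6%), and the unstable band
spans a factor e^1.21 ≈ 3.4 in k² — a moderately labyrinthine regime.  The
final call asks whether the true parameter pair sits inside the 95%
highest-density region of the lattice posterior built from the 20 images.

Model selection on a small freshly generated library:

```r
cfg <- selection_config(counts = c(turing = 16, kt = 16, gray_scott = 18,
                                   edwards_wilkinson = 8, eden = 10,
                                   dla = 8, l_system = 10, phase_field = 6),
                        size = 48, fast = TRUE)
man <- build_selection_dataset(cfg, out_dir = "library", seed = 42)
store <- encode_dataset(man, encoder_spec(input_size = 48),
                        blur_sigma = 0.75)
rk <- crop_scan_select(read_image(man$path[5]), store,
                       encoder_spec(input_size = 48), top_n = 3)
map_matrix(store, k = 20)["turing", ]
```

On this library the Turing row's two largest MAP@20 entries are the Turing
and kernel-based-Turing columns — the two mechanisms that generate
interchangeable patterns.

A thin command-line wrapper is installed at `inst/cli/patternfit`
(`patternfit generate|encode|select|stability|validate-linreg|run`).

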