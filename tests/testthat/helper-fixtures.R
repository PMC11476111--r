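# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) {
    .fixtures[[name]] <- force(expr)
  }
  .fixtures[[name]]
}

tiny_catalog <- function() fixture("tiny_catalog", default_catalog(3))

tiny_scenes <- function() fixture("tiny_scenes", {
  generate_dataset(tiny_catalog(), 40, scene_spec(), seed = 11)
})

tiny_kb <- function() fixture("tiny_kb", {
  build_knowledge_base(tiny_catalog(), seed = 42)
})

# The study corpus used by the directional ablation and empty-shot checks:
# 3 species, 200 scenes split 70/15/15, 500 training iterations.
study_corpus <- function() fixture("study_corpus", {
  scenes <- generate_dataset(tiny_catalog(), 200, scene_spec(), seed = 1)
  splits <- split_dataset(scenes, c(0.7, 0.15, 0.15), seed = 1)
  kb <- build_knowledge_base(tiny_catalog(), seed = 42)
  list(scenes = scenes, splits = splits, kb = kb)
})

# Pretrained (teacher-distilled) encoder for one seed, cached.
study_encoder <- function(seed) {
  fixture(paste0("encoder_", seed), {
    corp <- study_corpus()
    teacher <- make_teacher(corp$splits$train, corp$kb, seed = seed + 1000,
                            epochs = 15)
    pretrain_region_encoder(
      corp$splits$train, corp$kb, teacher,
      alignment_config(epochs = 15, seed = seed))$encoder
  })
}

# A trained detector of the given variant and seed on the study corpus.
study_model <- function(variant, seed) {
  fixture(paste0("model_", variant, "_", seed), {
    corp <- study_corpus()
    train_detector(corp$splits$train, corp$kb,
                   detector_config(variant = variant, iterations = 500,
                                   seed = seed),
                   encoder = study_encoder(seed))
  })
}

# Central-difference numeric gradient of a scalar function of a matrix or
# vector argument.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-8)
}

# Random small detection/GT instance for the AP oracle checks.
random_ap_instance <- function() {
  n_gt <- sample(1:4, 1)
  n_det <- sample(1:8, 1)
  gt <- data.frame(image_id = "img1", label = 1L,
                   xmin = runif(n_gt, 0, 50), ymin = runif(n_gt, 0, 50))
  gt$xmax <- gt$xmin + runif(n_gt, 5, 30)
  gt$ymax <- gt$ymin + runif(n_gt, 5, 30)
  base <- gt[sample(n_gt, n_det, replace = TRUE), ]
  det <- data.frame(image_id = "img1", label = 1L,
                    xmin = base$xmin + rnorm(n_det, 0, 6),
                    ymin = base$ymin + rnorm(n_det, 0, 6))
  det$xmax <- det$xmin + (base$xmax - base$xmin) * exp(rnorm(n_det, 0, 0.3))
  det$ymax <- det$ymin + (base$ymax - base$ymin) * exp(rnorm(n_det, 0, 0.3))
  det$score <- runif(n_det)
  list(det = det, gt = gt)
}

# Brute-force AP oracle: enumerate every rank cutoff of the ranked TP
# flags, compute recall/precision at each from first principles, and
# accumulate the staircase area.
brute_force_ap <- function(tp_flags, n_gt) {
  ap <- 0
  r_prev <- 0
  for (k in seq_along(tp_flags)) {
    tp_k <- sum(tp_flags[seq_len(k)])
    r_k <- tp_k / n_gt
    p_k <- tp_k / k
    ap <- ap + (r_k - r_prev) * p_k
    r_prev <- r_k
  }
  ap
}
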