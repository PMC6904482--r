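# Fixtures and independent oracles used across the suite.

# Minimal exam_match mock for FROC/FOM-level tests that do not need boxes.
mock_match <- function(hit_conf, fp_conf, n_lesions, exam_id = "E") {
  stopifnot(length(hit_conf) <= n_lesions)
  structure(list(
    exam_id = exam_id,
    hits = tibble::tibble(
      lesion_id = paste0("L", seq_along(hit_conf)),
      detection = seq_along(hit_conf),
      iou = rep(0.8, length(hit_conf)),
      confidence = hit_conf
    ),
    false_positives = tibble::tibble(
      detection = length(hit_conf) + seq_along(fp_conf),
      confidence = fp_conf
    ),
    missed = if (n_lesions > length(hit_conf)) {
      paste0("L", (length(hit_conf) + 1):n_lesions)
    } else character(),
    n_lesions = as.integer(n_lesions),
    n_detections = length(hit_conf) + length(fp_conf)
  ), class = "exam_match")
}

# Random list of mock matches (one per exam).
random_matches <- function(n_exams, max_lesions = 3L, max_fp = 3L) {
  lapply(seq_len(n_exams), function(i) {
    n_les <- sample.int(max_lesions + 1L, 1L) - 1L
    n_hit <- if (n_les > 0L) sample.int(n_les + 1L, 1L) - 1L else 0L
    n_fp <- sample.int(max_fp + 1L, 1L) - 1L
    mock_match(runif(n_hit), runif(n_fp), n_les, exam_id = paste0("E", i))
  })
}

# Brute-force JAFROC figure of merit: explicit psi double loop over every
# (image, lesion) pair. Stays independent of the findInterval-based path.
fom_brute <- function(matches) {
  r <- unlist(lapply(matches, function(m) {
    c(m$hits$confidence, rep(-Inf, length(m$missed)))
  }), use.names = FALSE)
  f <- vapply(matches, function(m) {
    if (nrow(m$false_positives)) max(m$false_positives$confidence) else -Inf
  }, numeric(1))
  total <- 0
  for (ri in r) for (fi in f) {
    total <- total + if (ri > fi) 1 else if (ri == fi) 0.5 else 0
  }
  total / (length(r) * length(f))
}

# Exhaustive maximum-cardinality one-to-one assignment given an eligibility
# matrix (detections x lesions); recursion over detections.
max_card_assignment <- function(elig) {
  n_det <- nrow(elig)
  n_les <- ncol(elig)
  if (n_det == 0L || n_les == 0L) return(0L)
  rec <- function(i, used) {
    if (i > n_det) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(elig[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  rec(1L, rep(FALSE, n_les))
}

# Random matching instance with pairwise-disjoint lesions: disjointness
# guarantees (via the triangle inequality of the Jaccard distance) that no
# detection can exceed IoU 0.5 with two lesions at once, so the greedy
# result must realize the exhaustive maximum cardinality.
random_match_instance <- function(max_side = 5L, field = 100) {
  n_les <- sample.int(max_side + 1L, 1L) - 1L
  repeat {
    w <- runif(n_les, 5, 20); h <- runif(n_les, 5, 20)
    x <- runif(n_les, 0, field - w); y <- runif(n_les, 0, field - h)
    les <- data.frame(lesion_id = sprintf("L%d", seq_len(n_les)),
                      x_min = x, y_min = y, x_max = x + w, y_max = y + h)
    if (n_les < 2L) break
    iou <- 0
    for (i in seq_len(n_les - 1L)) for (j in (i + 1L):n_les) {
      iou <- max(iou, reprocad::box_iou(les[i, ], les[j, ]))
    }
    if (iou == 0) break
  }
  n_det <- sample.int(max_side + 1L, 1L) - 1L
  det <- data.frame(x_min = double(), y_min = double(), x_max = double(),
                    y_max = double(), confidence = double())
  if (n_det > 0L) {
    anchor <- if (n_les > 0L) sample.int(n_les, n_det, replace = TRUE) else rep(NA, n_det)
    rows <- lapply(seq_len(n_det), function(k) {
      if (!is.na(anchor[k]) && runif(1) < 0.7) {   # perturbed copy of a lesion
        b <- les[anchor[k], ]
        dx <- runif(1, -6, 6); dy <- runif(1, -6, 6)
        data.frame(x_min = b$x_min + dx, y_min = b$y_min + dy,
                   x_max = b$x_max + dx, y_max = b$y_max + dy,
                   confidence = runif(1))
      } else {                                      # free-floating box
        w <- runif(1, 5, 20); h <- runif(1, 5, 20)
        x <- runif(1, 0, field - w); y <- runif(1, 0, field - h)
        data.frame(x_min = x, y_min = y, x_max = x + w, y_max = y + h,
                   confidence = runif(1))
      }
    })
    det <- do.call(rbind, rows)
  }
  list(lesions = les, detections = det)
}

# Small hand-built valid dataset: two patients, one shared lesion each,
# detections covering both exams of patient A and only the initial of B.
tiny_dataset <- function() {
  exams <- tibble::tibble(
    patient_id = c("A", "A", "B", "B"),
    exam_id = c("A-I", "A-F", "B-I", "B-F"),
    role = c("initial", "followup", "initial", "followup"),
    width = 100, height = 100
  )
  lesions <- tibble::tibble(
    exam_id = c("A-I", "A-F", "B-I", "B-F"),
    lesion_id = "L1",
    x_min = 10, y_min = 10, x_max = 30, y_max = 30,
    size_mm = 5
  )
  detections <- tibble::tibble(
    exam_id = c("A-I", "A-F", "B-I"),
    x_min = 11, y_min = 11, x_max = 31, y_max = 31,
    confidence = c(0.9, 0.8, 0.7)
  )
  cad_dataset(exams, lesions, detections)
}

# Direct Monte-Carlo draw of the shared-mixture detection mechanism, used
# as an oracle for the closed-form expected agreement (no boxes involved).
mechanism_ppa <- function(s, rho, n) {
  shared <- runif(n) < rho
  z <- rbinom(n, 1L, s) == 1L
  zi <- ifelse(shared, z, rbinom(n, 1L, s) == 1L)
  zf <- ifelse(shared, z, rbinom(n, 1L, s) == 1L)
  a <- sum(zi & zf); b <- sum(zi & !zf); cc <- sum(!zi & zf)
  100 * 2 * a / (2 * a + b + cc)
}

# Delta-method standard error of the measured PPA under the mechanism with
# per-lesion category probabilities pA (both) and pM (exactly one).
ppa_mc_se <- function(s, rho, n) {
  pA <- rho * s + (1 - rho) * s^2
  pM <- 2 * (1 - rho) * s * (1 - s)
  den <- (2 * pA + pM)^2
  gu <- 200 * pM / den
  gv <- -200 * pA / den
  sqrt((gu^2 * pA * (1 - pA) + gv^2 * pM * (1 - pM) - 2 * gu * gv * pA * pM) / n)
}

cppa_mc_se <- function(s, rho, n) {
  pA <- rho * s + (1 - rho) * s^2
  pM <- 2 * (1 - rho) * s * (1 - s)
  den <- (pA + pM)^2
  gu <- 100 * pM / den
  gv <- -100 * pA / den
  sqrt((gu^2 * pA * (1 - pA) + gv^2 * pM * (1 - pM) - 2 * gu * gv * pA * pM) / n)
}
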