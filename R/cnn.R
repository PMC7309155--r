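#' CNN classifier configuration
#'
#' Architecture and training hyper-parameters of the frame-level risk
#' classifier: stacked 2-D convolution stages (kernels spanning 3
#' channels x `kernel_time` samples, max pooling by `pool` along time)
#' feeding a three-layer dense network with a single sigmoid output.
#'
#' @param window_s Frame duration, s (default 20).
#' @param train_step_s Frame step for training data, s (default 10,
#'   i.e. 50% overlap); test/validation participants use non-overlapping
#'   frames (`step = window`).
#' @param conv_filters Filters per conv stage.
#' @param kernel_time Kernel extent along time, samples.
#' @param pool Max-pool factor(s) along time, recycled over the conv
#'   stages.
#' @param global_pool Average the final feature maps over all positions
#'   (translation-invariant per-filter features) instead of flattening
#'   them; participant-level discriminants (fluctuation magnitude and
#'   roughness) are position-free, and pooling removes the capacity to
#'   memorize frame positions.
#' @param stride Convolution stride(s) along time, recycled over the
#'   conv stages; a stride of 4 in the first stage reduces compute
#'   fourfold while the 5-sample kernels still cover every sample.
#' @param dense_widths Hidden dense layer widths (the output layer is
#'   appended automatically).
#' @param learning_rate,epochs,batch_size Adam optimizer settings.
#' @param weight_decay Decoupled L2 weight decay per step.
#' @param aug_scale_sigma Training-time augmentation: each frame-channel
#'   is multiplied by an independent lognormal gain `exp(N(0, sigma))`.
#'   Worn-sensor gain and coupling vary between sessions, and each
#'   participant's idiosyncratic per-channel amplitude signature is the
#'   easiest feature to memorize; gain jitter suppresses that route and
#'   favours scale-invariant (relative spectral) features. Only
#'   meaningful with `frame_scale = "global"` (per-frame normalization
#'   already cancels constant gains); 0 disables (default).
#' @param frame_scale `"frame"` (default): each frame-channel is
#'   normalized to zero mean and unit SD, so the network reads waveform
#'   *shape* (complexity/spectral content) rather than amplitude -
#'   amplitude is both the easiest participant signature to memorize and
#'   the most session-dependent quantity on a real sensor. `"global"`:
#'   channels keep their relative amplitudes (frozen training-set
#'   scaling).
#' @param class_weights Weight frames by inverse class prevalence so the
#'   minority fallers contribute equally to the loss (default TRUE; the
#'   default cohort has 15 faller vs 42 nonfaller training
#'   participants).
#' @param patience Early-stopping patience (epochs without validation
#'   improvement; the best weights are restored).
#' @param val_fraction Fraction of *training participants* held out as
#'   the early-stopping fold.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(window_s = 20, train_step_s = 10,
                       conv_filters = c(8, 16, 32), kernel_time = 5,
                       stride = c(4, 1, 1), pool = c(4, 4, 4),
                       global_pool = TRUE, dense_widths = c(32, 16),
                       learning_rate = 2e-3, epochs = 30, batch_size = 64,
                       weight_decay = 1e-4, aug_scale_sigma = 0,
                       frame_scale = "frame", class_weights = TRUE,
                       patience = 10, val_fraction = 0.25) {
  stopifnot(window_s > 0, train_step_s > 0, length(conv_filters) >= 1)
  structure(list(window_s = window_s, train_step_s = train_step_s,
                 conv_filters = conv_filters, kernel_time = kernel_time,
                 stride = stride, pool = pool, global_pool = global_pool,
                 dense_widths = dense_widths,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, weight_decay = weight_decay,
                 aug_scale_sigma = aug_scale_sigma,
                 frame_scale = frame_scale,
                 class_weights = class_weights, patience = patience,
                 val_fraction = val_fraction),
            class = "cnn_config")
}

#' Split a cohort into training and test/validation participants
#'
#' Randomly draws a class-balanced test set (default 8 fallers + 8
#' nonfallers) without replacement; all remaining participants form the
#' training set, so every participant - and hence every frame - falls on
#' exactly one side.
#'
#' @param cohort Cohort tibble (`participant_id`, `faller`, ...).
#' @param n_test_fallers,n_test_nonfallers Test-set class counts.
#' @param seed Integer seed.
#' @return A `cohort_split` list with `train_ids`, `test_ids`.
#' @export
split_cohort <- function(cohort, n_test_fallers = 8, n_test_nonfallers = 8,
                         seed) {
  fallers <- cohort$participant_id[cohort$faller == 1]
  nonfallers <- cohort$participant_id[cohort$faller == 0]
  if (length(fallers) < n_test_fallers || length(nonfallers) < n_test_nonfallers) {
    abort("not enough participants in a class for the requested test set")
  }
  test <- withr::with_seed(seed, c(
    if (n_test_fallers > 0) sample(fallers, n_test_fallers),
    if (n_test_nonfallers > 0) sample(nonfallers, n_test_nonfallers)))
  structure(list(train_ids = setdiff(cohort$participant_id, test),
                 test_ids = test),
            class = "cohort_split")
}

#' Build a frame dataset for the CNN
#'
#' Splits each participant's recording into fixed-duration frames and
#' standardizes each of the six channels (subtract mean, divide by SD)
#' with statistics computed on the training set only: pass `stats = NULL`
#' to compute them (training data), or the stats returned previously to
#' freeze them (test data). Standardization is needed because the
#' acceleration (m/s^2) and angular-velocity (deg/s) channels differ by
#' two orders of magnitude.
#'
#' Each frame is first centred per channel (its own mean removed): the
#' slowly wandering baseline of a worn inertial sensor (gravity
#' projection, gyro bias, low-frequency drift) is frame- and
#' participant-specific but carries no group information, and would
#' otherwise dominate the convolution responses.
#'
#' @param cohort Cohort tibble with `series` list column and `faller`.
#' @param window_s,step_s Frame geometry, seconds.
#' @param stats `NULL` or a previous result's `stats` element.
#' @param center_frames Remove each frame's per-channel mean (default
#'   TRUE).
#' @param frame_scale `"global"` (scale channels by the frozen
#'   training-set SDs) or `"frame"` (normalize each frame-channel to
#'   unit SD; see [cnn_config()]).
#' @return List: `x` ((6 x samples) x n_frames matrix, channel-major
#'   columns), `y` labels, `participant_id` per frame, `stats`
#'   (per-channel mean/sd), `height`, `width`.
#' @export
make_frame_dataset <- function(cohort, window_s = 20, step_s = 10,
                               stats = NULL, center_frames = TRUE,
                               frame_scale = c("global", "frame")) {
  frame_scale <- match.arg(frame_scale)
  frames <- bind_rows(pmap(
    list(cohort$series, cohort$participant_id, cohort$faller),
    function(s, id, lb) split_frames(s, window_s = window_s, step_s = step_s,
                                     participant_id = id, label = lb)))
  if (!nrow(frames)) abort("no frames produced; recordings too short?")
  width <- ncol(frames$data[[1]])
  x <- vapply(frames$data, as.vector, numeric(6 * width))
  nf <- ncol(x)
  if (center_frames || frame_scale == "frame") {
    arr <- array(x, c(6L, width, nf))
    mu_fr <- colMeans(aperm(arr, c(2, 1, 3)))           # (6, n_frames)
    x <- x - as.vector(aperm(array(mu_fr, c(6L, nf, width)), c(1, 3, 2)))
  }
  if (frame_scale == "frame") {
    arr <- array(x * x, c(6L, width, nf))
    sd_fr <- sqrt(colMeans(aperm(arr, c(2, 1, 3))))     # (6, n_frames)
    sd_fr[sd_fr == 0] <- 1
    x <- x / as.vector(aperm(array(sd_fr, c(6L, nf, width)), c(1, 3, 2)))
  }
  if (is.null(stats)) {
    ch_of_row <- rep(seq_len(6), times = width)
    mu <- vapply(seq_len(6), function(cl) mean(x[ch_of_row == cl, ]), 0)
    sig <- vapply(seq_len(6), function(cl) sd(x[ch_of_row == cl, ]), 0)
    stats <- list(mean = mu, sd = sig)
  }
  x <- (x - stats$mean) / stats$sd  # rows cycle over channels, so recycle
  list(x = x, y = frames$label, participant_id = frames$participant_id,
       stats = stats, height = 6L, width = width)
}

#' Train the frame-level CNN
#'
#' Adam on binary cross-entropy. A fraction of the *training
#' participants* is held out as an early-stopping fold (no participant's
#' frames appear on both sides); training stops when the fold's loss has
#' not improved for `patience` epochs and the best weights are restored.
#' Fully deterministic given `seed`.
#'
#' @param dataset A [make_frame_dataset()] result (training frames).
#' @param config A [cnn_config()].
#' @param seed Integer seed for initialization, shuffling and the fold
#'   draw.
#' @return A `gait_cnn` model (weights, plan, config, stats, history).
#' @export
train_cnn <- function(dataset, config = cnn_config(), seed = 1L) {
  y <- dataset$y
  if (length(unique(y)) < 2) {
    abort("training frames must contain both classes",
          class = "gaitrisk_single_class_error")
  }
  plan <- nn_plan(dataset$height, dataset$width, config$conv_filters,
                  config$kernel_time, config$pool, config$dense_widths,
                  global_pool = config$global_pool, stride = config$stride)
  withr::with_seed(seed, {
    ids <- unique(dataset$participant_id)
    n_val <- max(1L, round(config$val_fraction * length(ids)))
    val_ids <- sample(ids, n_val)
    val <- dataset$participant_id %in% val_ids
    if (length(unique(y[!val])) < 2) val[] <- FALSE  # degenerate fold
    xtr <- dataset$x[, !val, drop = FALSE]
    ytr <- y[!val]
    xva <- dataset$x[, val, drop = FALSE]
    yva <- y[val]
    # inverse-prevalence class weights (mean 1) counter the faller /
    # nonfaller imbalance of the training cohort
    wcl <- if (config$class_weights) {
      prev <- mean(ytr)
      c(0.5 / (1 - prev), 0.5 / prev)
    } else {
      c(1, 1)
    }
    wtr <- wcl[ytr + 1]
    wva <- wcl[yva + 1]
    va_ids <- dataset$participant_id[val]
    aug_rows <- rep(seq_len(6), dataset$width)
    ws <- nn_init(plan)
    m <- adam_init(ws)
    v <- adam_init(ws)
    best <- list(loss = Inf, ws = ws, epoch = 0L)
    history <- tibble(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
    t_step <- 0L
    wait <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(ncol(xtr))
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        xb <- xtr[, bi, drop = FALSE]
        yb <- ytr[bi]
        wb <- wtr[bi]
        if (config$aug_scale_sigma > 0) {
          gain <- matrix(exp(rnorm(6 * length(bi), 0, config$aug_scale_sigma)),
                         6, length(bi))
          xb <- xb * gain[aug_rows, , drop = FALSE]
        }
        fw <- nn_forward(xb, plan, ws, keep = TRUE)
        loss <- bce_loss(fw$p, yb, wb)
        if (!is.finite(loss)) {
          abort(sprintf("non-finite training loss at epoch %d", ep))
        }
        gr <- nn_backward(xb, yb, plan, ws, fw, wb)
        t_step <- t_step + 1L
        st <- adam_step(ws, gr, m, v, config$learning_rate, t_step,
                        weight_decay = config$weight_decay)
        ws <- st$ws; m <- st$m; v <- st$v
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      # early-stopping criterion: participant-level balanced error on the
      # held-out fold (the quantity the experiment reports), with the
      # weighted frame loss as tie-breaker
      vloss <- if (ncol(xva)) {
        pv <- nn_forward(xva, plan, ws)
        ms <- tapply(pv, va_ids, mean)
        tv <- tapply(yva, va_ids, function(z) z[1])
        bacc <- (mean(ms[tv == 1] > 0.5, na.rm = TRUE) +
                   mean(ms[tv == 0] <= 0.5, na.rm = TRUE)) / 2
        if (!is.finite(bacc)) bacc <- mean((ms > 0.5) == (tv == 1))
        (1 - bacc) + 0.001 * bce_loss(pv, yva, wva)
      } else {
        ep_loss / nb
      }
      history <- bind_rows(history,
                           tibble(epoch = ep, train_loss = ep_loss / nb,
                                  val_loss = vloss))
      if (vloss < best$loss - 1e-5) {
        best <- list(loss = vloss, ws = ws, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(weights = best$ws, plan = plan, config = config,
                   stats = dataset$stats, history = history,
                   best_epoch = best$epoch, seed = seed),
              class = "gait_cnn")
  })
}

#' @export
print.gait_cnn <- function(x, ...) {
  np <- sum(rapply(x$weights, length, how = "unlist"))
  cat(sprintf("Frame-level CNN: %d conv stages, %d parameters, best epoch %d\n",
              length(x$plan$stages), np, x$best_epoch))
  invisible(x)
}

#' Glance at a trained CNN
#' @param x A `gait_cnn`.
#' @param ... Ignored.
#' @return One-row tibble: epochs run, best epoch, final losses.
#' @export
glance.gait_cnn <- function(x, ...) {
  h <- x$history
  tibble(epochs = nrow(h), best_epoch = x$best_epoch,
         train_loss = h$train_loss[nrow(h)], val_loss = min(h$val_loss))
}

#' Frame-level risk scores
#'
#' @param object A trained `gait_cnn`.
#' @param x Frame matrix ((6 x samples) x n, already standardized with
#'   the model's stats) or a [make_frame_dataset()] result.
#' @param ... Ignored.
#' @return Numeric scores in \[0, 1\], one per frame.
#' @export
predict.gait_cnn <- function(object, x, ...) {
  if (is.list(x)) x <- x$x
  nn_forward(x, object$plan, object$weights)
}

#' Participant-level risk from frame scores
#'
#' The participant's risk score is the arithmetic mean of the model's
#' predictions over all their frames; a mean strictly greater than 0.5
#' denotes a participant at risk of fall.
#'
#' @param model A trained `gait_cnn`.
#' @param dataset A [make_frame_dataset()] result covering one or more
#'   participants (built with the model's frozen `stats`).
#' @param scores Optional precomputed frame scores (bypasses the model).
#' @return Tibble: `participant_id`, `mean_score`, `risk`, `n_frames`.
#' @export
participant_risk <- function(model, dataset, scores = NULL) {
  if (!length(dataset$y)) abort("no frames to score")
  if (is.null(scores)) scores <- predict(model, dataset$x)
  stopifnot(length(scores) == length(dataset$participant_id))
  tibble(participant_id = dataset$participant_id, score = scores) %>%
    group_by(.data$participant_id) %>%
    summarise(mean_score = mean(.data$score), n_frames = n(),
              .groups = "drop") %>%
    mutate(risk = as.integer(.data$mean_score > 0.5))
}

#' Run the full AI classification experiment on a cohort
#'
#' End-to-end pipeline: balanced participant split (default 8 + 8 test),
#' overlapping training frames / non-overlapping test frames,
#' standardization frozen on the training set, CNN training, mean-score
#' participant classification and diagnostic evaluation of the test set.
#'
#' @param cohort Cohort tibble with `series`, `faller`.
#' @param config A [cnn_config()].
#' @param seed Integer seed driving the split and the training run.
#' @param n_test_fallers,n_test_nonfallers Test-set composition.
#' @return List: `split`, `model`, `risks` (per test participant),
#'   `confusion`, `metrics`.
#' @export
run_ai_experiment <- function(cohort, config = cnn_config(), seed,
                              n_test_fallers = 8, n_test_nonfallers = 8) {
  split <- split_cohort(cohort, n_test_fallers, n_test_nonfallers, seed = seed)
  train <- cohort %>% filter(.data$participant_id %in% split$train_ids)
  test <- cohort %>% filter(.data$participant_id %in% split$test_ids)
  dtrain <- make_frame_dataset(train, window_s = config$window_s,
                               step_s = config$train_step_s,
                               frame_scale = config$frame_scale)
  model <- train_cnn(dtrain, config, seed = seed + 1L)
  dtest <- make_frame_dataset(test, window_s = config$window_s,
                              step_s = config$window_s,
                              stats = dtrain$stats,
                              frame_scale = config$frame_scale)
  risks <- participant_risk(model, dtest) %>%
    left_join(test %>% select("participant_id", "faller"),
              by = "participant_id")
  ev <- evaluate_classifier(risks$risk, risks$faller)
  list(split = split, model = model, risks = risks,
       confusion = ev$confusion, metrics = ev$metrics)
}
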