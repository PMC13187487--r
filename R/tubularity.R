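# Multiscale Hessian ridge ("tubularity") filters for curvilinear vessel
# enhancement: Meijering neuriteness (default), Frangi vesselness, Sato
# line filter, and Jerman's eigenvalue-ratio filter. All operate in
# bright-ridge polarity, take the per-pixel maximum over a sigma ladder,
# and rescale the final response to [0, 255] so that the segmentation
# threshold is expressed on a fixed 8-bit scale.

#' Segmentation parameters
#'
#' @param meijering_threshold Response threshold on the [0, 255]-rescaled
#'   multiscale ridge response (default 10; `>` keeps).
#' @param sigma_min,sigma_max,sigma_step Scale ladder in pixels
#'   (defaults 3, 8, 1).
#' @param min_object_px Foreground components with area below this are
#'   removed (default 50).
#' @param max_hole_px Background holes with area below this are filled
#'   (default 200).
#' @param filter_name One of "meijering", "frangi", "sato", "jerman".
#' @param combine_with_otsu How the thresholded ridge response is combined
#'   with the Otsu mask: "intersection" (default), "union", "meijering_only".
#' @export
segmentation_params <- function(meijering_threshold = 10,
                                sigma_min = 3, sigma_max = 8, sigma_step = 1,
                                min_object_px = 50L, max_hole_px = 200L,
                                filter_name = c("meijering", "frangi", "sato", "jerman"),
                                combine_with_otsu = c("intersection", "union", "meijering_only")) {
  filter_name <- match.arg(filter_name)
  combine_with_otsu <- match.arg(combine_with_otsu)
  if (sigma_min > sigma_max) stop("sigma_min must be <= sigma_max")
  if (sigma_step <= 0) stop("sigma_step must be > 0")
  if (meijering_threshold < 0 || meijering_threshold > 255)
    stop("meijering_threshold must be in [0, 255]")
  structure(list(meijering_threshold = meijering_threshold,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 sigma_step = sigma_step,
                 min_object_px = as.integer(min_object_px),
                 max_hole_px = as.integer(max_hole_px),
                 filter_name = filter_name,
                 combine_with_otsu = combine_with_otsu),
            class = "zv_segmentation_params")
}

# Scale-normalised Hessian (gamma = 2): sigma^2 * second Gaussian
# derivatives. x runs along columns, y along rows.
hessian_at_sigma <- function(img, sigma) {
  g0 <- gauss_kernel(sigma, 0L)
  g2 <- gauss_kernel(sigma, 2L)
  g1 <- gauss_kernel(sigma, 1L)
  s2 <- sigma^2
  list(
    xx = s2 * conv_sep(img, g0, g2),
    yy = s2 * conv_sep(img, g2, g0),
    xy = s2 * conv_sep(img, g1, g1)
  )
}

# Eigenvalues of the 2x2 symmetric Hessian, split by |.|:
# lo = smaller magnitude, hi = larger magnitude.
hessian_eigenvalues <- function(H) {
  a <- (H$xx + H$yy) / 2
  d <- sqrt(((H$xx - H$yy) / 2)^2 + H$xy^2)
  l1 <- a + d; l2 <- a - d
  swap <- abs(l1) > abs(l2)
  lo <- ifelse(swap, l2, l1)
  hi <- ifelse(swap, l1, l2)
  list(lo = lo, hi = hi)
}

meijering_response <- function(ev) {
  # Neuriteness: modified eigenvalues l' = l + l_other/3; take the one of
  # largest magnitude; bright ridges give negative values. The raw
  # magnitude is returned; the final [0, 255] rescale over the multiscale
  # maximum performs the normalisation by the strongest ridge.
  m1 <- ev$lo + ev$hi / 3
  m2 <- ev$hi + ev$lo / 3
  lam <- ifelse(abs(m1) > abs(m2), m1, m2)
  pmax(-lam, 0)
}

frangi_response <- function(ev, beta = 0.5) {
  S2 <- ev$lo^2 + ev$hi^2
  c2 <- max(S2) / 4                       # (half of max Frobenius norm)^2
  if (c2 <= 0) return(ev$lo * 0)
  Rb2 <- ifelse(ev$hi != 0, (ev$lo / ev$hi)^2, 0)
  v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
  ifelse(ev$hi < 0, v, 0)                 # bright ridges only
}

sato_response <- function(ev, alpha1 = 0.5, alpha2 = 2) {
  lc <- -ev$hi                            # > 0 on bright ridges
  alpha <- ifelse(ev$lo <= 0, alpha1, alpha2)
  v <- ifelse(lc > 0, lc * exp(-ev$lo^2 / (2 * (alpha * lc)^2)), 0)
  v
}

jerman_response <- function(ev, tau = 0.5) {
  x <- pmax(-ev$hi, 0)                    # bright-ridge magnitude
  mx <- max(x)
  if (mx <= 0) return(x)
  lrho <- ifelse(x > tau * mx, x, ifelse(x > 0, tau * mx, 0))
  v <- ifelse(x <= 0 | lrho <= 0, 0,
              ifelse(x >= lrho / 2, 1,
                     x^2 * (lrho - x) * (3 / (x + lrho))^3))
  v
}

#' Multiscale tubularity (ridge) filter
#'
#' Computes the chosen Hessian-based ridge response at each sigma in the
#' ladder, takes the per-pixel maximum across scales, and rescales the
#' result to [0, 255]. All filters respond to bright curvilinear structures
#' on a dark background; a constant image returns an all-zero response.
#'
#' @param image An 8-bit `zv_projection` (typically CLAHE-enhanced).
#' @param params A [segmentation_params()] object.
#' @param rescale Rescale the response to [0, 255] (default). Disable to
#'   obtain the raw scale-normalised response (useful for comparing scales).
#' @return Numeric matrix in [0, 255] (or raw units if `rescale = FALSE`).
#' @export
tubularity_filter <- function(image, params = segmentation_params(),
                              rescale = TRUE) {
  px <- if (inherits(image, "zv_projection")) {
    if (image$bit_depth != 8) stop("tubularity_filter expects an 8-bit image")
    image$pixels
  } else image
  sigmas <- seq(params$sigma_min, params$sigma_max, by = params$sigma_step)
  fn <- switch(params$filter_name,
               meijering = meijering_response,
               frangi = frangi_response,
               sato = sato_response,
               jerman = jerman_response,
               stop("unknown filter_name: ", params$filter_name))
  resp <- matrix(0, nrow(px), ncol(px))
  img <- px * 1.0
  for (s in sigmas) {
    ev <- hessian_eigenvalues(hessian_at_sigma(img, s))
    resp <- pmax(resp, fn(ev))
  }
  if (rescale) rescale_0_255(resp) else resp
}

rescale_0_255 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(m * 0)
  (m - lo) / (hi - lo) * 255
}
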