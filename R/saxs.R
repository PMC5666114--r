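# Debye-formula scattering profiles, chi-square fitting with an analytic
# scale factor, and the standard Guinier/Kratky/Porod descriptors.

#' Form factor table
#'
#' Per-element scattering amplitudes for the Debye sum. The package's default
#' model uses *constant* (q-independent) reduced scattering lengths: vacuum
#' electron counts minus the electrons of the displaced solvent
#' (0.334 e/A^3 times a per-element displaced volume). Beads (`RES`) carry a
#' single effective per-residue scattering length. Because every fit applies
#' a free multiplicative scale factor, only relative amplitudes matter; the
#' q-dependence of atomic form factors and the excluded-volume/hydration
#' adjustments of full-featured scattering calculators are deliberately out
#' of scope (see the methods vignette).
#'
#' @param reduced Apply the displaced-solvent correction (default TRUE).
#' @return Named numeric vector of f(0) values per element label.
#' @export
form_factor_table <- function(reduced = TRUE) {
  z <- c(H = 1, D = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34, RES = 10)
  if (!reduced) return(z)
  # displaced volumes (A^3): Fraser-style; solvent density 0.334 e/A^3
  vol <- c(H = 5.15, D = 5.15, C = 16.44, N = 2.49, O = 9.13, S = 19.86,
           P = 5.73, SE = 9.00, RES = 0)
  f <- z - 0.334 * vol
  f[["RES"]] <- 10  # effective reduced residue scattering, arbitrary units
  f
}

atom_form_factors <- function(atoms, ff = form_factor_table()) {
  f <- ff[toupper(atoms$element)]
  if (anyNA(f)) {
    abort(paste0("No form factor for element(s): ",
                 paste(unique(atoms$element[is.na(f)]), collapse = ", ")))
  }
  unname(f)
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)

has_sigma <- function(profile) "sigma" %in% names(profile)

#' Theoretical scattering profile by the Debye formula
#'
#' Computes the orientationally averaged intensity
#' `I(q) = sum_i sum_j f_i f_j sin(q r_ij) / (q r_ij)` of a rigid particle.
#' With `bin_width > 0` the double sum is evaluated through a weighted
#' pair-distance histogram with a second-order expansion about each bin's
#' mean distance, which turns an O(N^2 x Nq) computation into
#' O(N^2 + Nbins x Nq) at ~1e-7 relative accuracy; `bin_width = 0` runs the
#' exact double sum. For a symmetric assembly with a generator, the histogram
#' additionally exploits the fact that the cross-distance set between copies
#' i and j depends only on j - i, reducing the pair work by about n_units/2.
#'
#' @param x Atom tibble or `assembly`.
#' @param q Momentum-transfer grid, 1/Angstrom (may start at 0).
#' @param ff Form factor table, see [form_factor_table()].
#' @param bin_width Pair-distance histogram bin, Angstrom; 0 for the exact
#'   double sum. Default 0.1.
#' @return Profile tibble with columns `q`, `I` (attribute `label`).
#' @export
debye_profile <- function(x, q, ff = form_factor_table(), bin_width = 0.1) {
  stopifnot(all(is.finite(q)), bin_width >= 0)
  if (is_assembly(x) && !is.null(x$generator) && bin_width > 0) {
    I <- debye_symmetric(x, q, ff, bin_width)
  } else {
    atoms <- if (is_assembly(x)) assembly_atoms(x) else x
    if (!nrow(atoms)) abort("debye_profile needs at least one atom.")
    f <- atom_form_factors(atoms, ff)
    X <- atom_coords(atoms)
    if (bin_width == 0) {
      I <- as.numeric(debye_exact_cpp(X, f, q))
    } else {
      h <- pair_hist_weighted(X, f, bin_width)
      I <- hist_to_intensity(h, f2_sum = sum(f^2), q = q)
    }
  }
  out <- tibble(q = as.numeric(q), I = I)
  attr(out, "label") <- if (is_assembly(x)) "assembly model" else
    attr(x, "source_label") %||% "model"
  out
}

# second derivative of sinc, for the per-bin Taylor correction
sinc2d <- function(x) {
  ifelse(abs(x) < 1e-4, -1 / 3 + x^2 / 10,
         -sin(x) / x - 2 * cos(x) / x^2 + 2 * sin(x) / x^3)
}

# h is the 3-row (sum w, sum w*d, sum w*d^2) histogram matrix; the Debye
# kernel is expanded to second order about each bin's weighted mean distance,
# so the binned sum matches the exact double sum to O(bin^3).
hist_to_intensity <- function(h, f2_sum, q) {
  as.numeric(hist_intensity_cpp(h, f2_sum, q))
}

add_hist <- function(a, b) {
  if (ncol(b) > ncol(a)) a <- cbind(a, matrix(0, nrow(a), ncol(b) - ncol(a)))
  a[, seq_len(ncol(b))] <- a[, seq_len(ncol(b))] + b
  a
}

# histogram Debye for a generator-symmetric assembly: the cross-distance set
# between copies i and j depends only on j - i, so one cross histogram per
# offset (weighted by its multiplicity) covers all unit pairs
debye_symmetric <- function(assembly, q, ff, bin_width) {
  f <- atom_form_factors(assembly$seed, ff)
  U <- atom_coords(assembly$seed)
  n <- assembly$n_units
  h <- pair_hist_weighted(U, f, bin_width) * n
  for (k in seq_len(n - 1)) {
    p <- assembly$placements[[k + 1]]
    Uk <- sweep(U %*% t(p$R), 2, p$t, "+")
    h <- add_hist(h, cross_hist_weighted(U, f, Uk, f, bin_width)$hist * (n - k))
  }
  hist_to_intensity(h, f2_sum = n * sum(f^2), q = q)
}

#' Read and write 3-column SAXS profiles
#'
#' Whitespace-separated text with columns q (1/Angstrom), I, and optionally
#' sigma; `#` comment lines ignored — the common exchange dialect for
#' experimental profiles.
#'
#' @param path File path.
#' @param profile Profile tibble with `q`, `I` and optionally `sigma`.
#' @return `read_saxs_profile` returns a profile tibble.
#' @export
read_saxs_profile <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (!ncol(raw) %in% 2:3) {
    abort(sprintf("Expected 2 or 3 whitespace-separated columns in '%s', found %d.",
                  path, ncol(raw)))
  }
  names(raw) <- c("q", "I", "sigma")[seq_len(ncol(raw))]
  out <- as_tibble(raw)
  if (has_sigma(out) && all(is.na(out$sigma))) out$sigma <- NULL
  if (is.unsorted(out$q, strictly = TRUE)) abort("q grid must be strictly increasing.")
  if (has_sigma(out) && any(out$sigma <= 0, na.rm = TRUE)) {
    abort("sigma column must be positive where present.")
  }
  attr(out, "label") <- basename(path)
  out
}

#' @rdname read_saxs_profile
#' @export
write_saxs_profile <- function(profile, path) {
  cols <- intersect(c("q", "I", "sigma"), names(profile))
  hdr <- paste0("# openring profile: ", paste(cols, collapse = " "))
  lines <- do.call(sprintf, c(list(fmt = paste(rep("%.8g", length(cols)), collapse = " ")),
                              unname(as.list(profile[cols]))))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Fit a model profile to an experimental profile by reduced chi-square
#'
#' Interpolates the model onto the experiment's q grid (linearly in
#' (q, log I); extrapolation is forbidden), optimizes the scale factor in
#' closed form, `c = sum(I_exp I_mod / s^2) / sum(I_mod^2 / s^2)`, and
#' reports the reduced chi-square
#' `chi2 = 1/(N-1) sum((I_exp - c I_mod)^2 / s^2)`.
#'
#' @param model Profile tibble (`q`, `I`), e.g. from [debye_profile()].
#' @param experiment Profile tibble with `q`, `I`, `sigma`.
#' @param model_id Optional identifier carried into the result.
#' @return Object of class `saxs_fit`: `scale`, `chi2`, `n`, `model_id`, and
#'   `data` (tibble with `q`, `I_exp`, `sigma`, `I_model` scaled).
#' @export
chi_square_fit <- function(model, experiment, model_id = NULL) {
  if (!has_sigma(experiment)) abort("Experimental profile must carry a sigma column.")
  if (min(experiment$q) < min(model$q) - 1e-12 ||
      max(experiment$q) > max(model$q) + 1e-12) {
    abort(sprintf("Model q range [%.4g, %.4g] does not cover experiment [%.4g, %.4g].",
                  min(model$q), max(model$q), min(experiment$q), max(experiment$q)))
  }
  Im <- interp_profile(model, experiment$q)
  Ie <- experiment$I
  s2 <- experiment$sigma^2
  cc <- sum(Ie * Im / s2) / sum(Im^2 / s2)
  n <- length(Ie)
  chi2 <- sum((Ie - cc * Im)^2 / s2) / (n - 1)
  structure(list(scale = cc, chi2 = chi2, n = n, model_id = model_id,
                 data = tibble(q = experiment$q, I_exp = Ie,
                               sigma = experiment$sigma, I_model = cc * Im)),
            class = "saxs_fit")
}

interp_profile <- function(model, q_out) {
  if (all(model$I > 0)) {
    exp(stats::approx(model$q, log(model$I), xout = q_out, rule = 1)$y)
  } else {
    stats::approx(model$q, model$I, xout = q_out, rule = 1)$y
  }
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("<saxs_fit> chi2 = %.4f, scale = %.4g, n = %d\n", x$chi2, x$scale, x$n))
  invisible(x)
}

#' @export
glance.saxs_fit <- function(x, ...) {
  tibble(chi2 = x$chi2, scale = x$scale, n = x$n,
         model_id = x$model_id %||% NA_character_)
}

#' @export
tidy.saxs_fit <- function(x, ...) x$data

#' @export
autoplot.saxs_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$I_exp,
                                          ymin = .data$I_exp - .data$sigma,
                                          ymax = .data$I_exp + .data$sigma),
                             colour = "firebrick", size = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$I_model), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)",
                  title = sprintf("chi^2 = %.3f", object$chi2)) +
    ggplot2::theme_minimal()
}

#' Guinier analysis
#'
#' Weighted linear regression of `ln I` on `q^2` over the low-q region
#' `q * Rg < qrg_max`, iterating the range from an initial estimate until the
#' point selection is stable. Returns the radius of gyration and forward
#' scattering.
#'
#' @param profile Profile tibble (`q`, `I`, optional `sigma`).
#' @param qrg_max Upper limit of q*Rg for the fitted region (default 1.3).
#' @return List of class `guinier_fit`: `Rg` (A), `I0`, `guinier_range`
#'   (q limits used), `n_points`.
#' @export
guinier_fit <- function(profile, qrg_max = 1.3) {
  d <- profile[profile$q > 0 & profile$I > 0, ]
  if (nrow(d) < 5) abort("Guinier fit needs at least 5 positive-I points with q > 0.")
  w <- if (has_sigma(d)) (d$I / d$sigma)^2 else rep(1, nrow(d))
  fit_region <- function(keep) {
    q2 <- d$q[keep]^2
    co <- unname(stats::lm.wfit(cbind(1, q2), log(d$I[keep]), w[keep])$coefficients)
    list(I0 = exp(co[1]), Rg = sqrt(max(0, -3 * co[2])))
  }
  keep <- seq_len(min(max(5L, nrow(d) %/% 10L), nrow(d)))
  est <- fit_region(keep)
  for (it in 1:25) {
    if (est$Rg <= 0) { keep_new <- seq_len(min(10L, nrow(d))) } else {
      keep_new <- which(d$q * est$Rg < qrg_max)
    }
    if (length(keep_new) < 5) break
    if (identical(keep_new, keep)) break
    keep <- keep_new
    est <- fit_region(keep)
  }
  if (length(keep) < 5 || est$Rg <= 0) {
    abort("No valid Guinier region found (fewer than 5 usable points or negative slope).")
  }
  structure(list(Rg = est$Rg, I0 = est$I0,
                 guinier_range = range(d$q[keep]), n_points = length(keep),
                 qrg_max = qrg_max), class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg = %.3f A, I0 = %.4g (%d pts, q in [%.4g, %.4g])\n",
              x$Rg, x$I0, x$n_points, x$guinier_range[1], x$guinier_range[2]))
  invisible(x)
}

#' @export
glance.guinier_fit <- function(x, ...) {
  tibble(Rg = x$Rg, I0 = x$I0, n_points = x$n_points,
         q_min = x$guinier_range[1], q_max = x$guinier_range[2])
}

#' Kratky curve and Porod exponent
#'
#' Returns the Kratky transform `(q, q^2 I(q))` — the shape diagnostic for
#' foldedness — and the Porod exponent, the magnitude of the high-q log-log
#' slope of I(q) (about 4 for compact particles). The default Porod range is
#' the last decade of q at which the signal is informative (`I > 10 sigma`
#' where sigma is available, otherwise the last decade of the grid).
#'
#' @param profile Profile tibble.
#' @param porod_q_range Optional `c(qmin, qmax)` for the exponent fit.
#' @return List of class `kratky_porod`: `kratky` (tibble `q`, `q2I`),
#'   `porod_exponent`, `porod_range`.
#' @export
kratky_porod <- function(profile, porod_q_range = NULL) {
  d <- profile[profile$q > 0 & profile$I > 0, ]
  if (is.null(porod_q_range)) {
    qmax <- if (has_sigma(d)) {
      ok <- d$I > 10 * d$sigma
      if (!any(ok)) max(d$q) else max(d$q[ok])
    } else max(d$q)
    porod_q_range <- c(qmax / 10, qmax)
  }
  sel <- d$q >= porod_q_range[1] & d$q <= porod_q_range[2]
  if (sum(sel) < 5) abort("Porod fit needs at least 5 points in the q range.")
  co <- stats::lm(log(I) ~ log(q), data = d[sel, ])$coefficients
  structure(list(
    kratky = tibble(q = d$q, q2I = d$q^2 * d$I),
    porod_exponent = -unname(co[2]),
    porod_range = porod_q_range), class = "kratky_porod")
}

#' @export
print.kratky_porod <- function(x, ...) {
  cat(sprintf("<kratky_porod> Porod exponent %.3f over q in [%.4g, %.4g]\n",
              x$porod_exponent, x$porod_range[1], x$porod_range[2]))
  invisible(x)
}

#' Kratky plot
#'
#' @param x A `kratky_porod` object or a profile tibble.
#' @param ... Ignored.
#' @return ggplot object.
#' @export
plot_kratky <- function(x, ...) {
  k <- if (inherits(x, "kratky_porod")) x$kratky else
    tibble(q = x$q, q2I = x$q^2 * x$I)
  ggplot2::ggplot(k, ggplot2::aes(.data$q, .data$q2I)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = expression(q^2 * I(q)),
                  title = "Kratky plot") +
    ggplot2::theme_minimal()
}
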