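# internal helpers

.stop2 <- function(class, fmt, ...) {
    stop(structure(class = c(class, "rhizofun_error", "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.degenerate_range <- function(what) {
    .stop2("rhizofun_degenerate_range",
           "degenerate range (max == min) in %s; drop the variable or abort",
           what)
}

.check_seed <- function(seed) {
    if (!is.null(seed)) {
        if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
            stop("seed must be a single finite number")
        set.seed(as.integer(seed))
    }
    invisible(NULL)
}

.as_dist_matrix <- function(d, arg = "distance") {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m))
        stop(sprintf("%s must be square", arg))
    if (max(abs(m - t(m))) > 1e-8)
        stop(sprintf("%s must be symmetric", arg))
    if (any(abs(diag(m)) > 1e-8))
        stop(sprintf("%s must have a zero diagonal", arg))
    m
}
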