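#' Completion backend configuration
#'
#' Configures how prompts are completed. The `"mock"` backend returns canned
#' completions keyed by exact prompt text and makes the whole pipeline
#' deterministic and offline-testable; `"echo"` returns the prompt unchanged;
#' `"function"` delegates to an arbitrary R function; `"http"` posts to a
#' chat-completion JSON endpoint (optional, nothing in the package depends on
#' it). The creativity (temperature) default is the lowest supported value,
#' 0, to limit hallucinated structure.
#'
#' @param backend One of `"mock"`, `"echo"`, `"function"`, `"http"`.
#' @param model Model identifier passed to live backends (default
#'   `"gpt-3.5-turbo"`).
#' @param temperature Sampling temperature; defaults to the minimum, 0.
#' @param max_tokens Maximum completion length requested from live backends.
#' @param timeout Per-request timeout in seconds.
#' @param retries Number of retries after a transport failure.
#' @param completions Named list/character vector of prompt -> completion for
#'   the mock backend (see [read_completions()]).
#' @param fallback Mock completion used when a prompt has no entry (default
#'   `""`, which parses to an empty instance).
#' @param fn Completion function `function(prompt) -> text` for the
#'   `"function"` backend.
#' @param url Endpoint for the `"http"` backend.
#' @param api_key_env Name of the environment variable holding the API key.
#' @return A `pkb_completion_config`.
#' @export
completion_config <- function(backend = c("mock", "echo", "function", "http"),
                              model = "gpt-3.5-turbo",
                              temperature = 0,
                              max_tokens = 1024L,
                              timeout = 60,
                              retries = 2L,
                              completions = list(),
                              fallback = "",
                              fn = NULL,
                              url = NULL,
                              api_key_env = "COMPLETION_API_KEY") {
  backend <- match.arg(backend)
  if (backend == "function" && !is.function(fn)) {
    pkb_stop("pkb_invalid_configuration", "'function' backend requires fn")
  }
  structure(
    list(
      backend = backend, model = model, temperature = temperature,
      max_tokens = max_tokens, timeout = timeout, retries = as.integer(retries),
      completions = as.list(completions), fallback = fallback,
      fn = fn, url = url, api_key_env = api_key_env
    ),
    class = "pkb_completion_config"
  )
}

#' Complete a prompt
#'
#' Sends a prompt to the configured backend and records the verbatim raw
#' completion together with provenance (backend, attempts, wall time). The
#' prompt is never mutated. Transport failures are retried up to
#' `config$retries` times; exhausted retries raise a backend-unavailable
#' error. An empty completion is not an error: downstream parsing yields an
#' empty instance.
#'
#' @param prompt Prompt text.
#' @param config A [completion_config()].
#' @return A `pkb_completion` record with fields `prompt`, `raw`, `backend`,
#'   `model`, `elapsed`, `attempts`.
#' @export
complete <- function(prompt, config = completion_config()) {
  stopifnot(inherits(config, "pkb_completion_config"))
  t0 <- proc.time()[["elapsed"]]
  attempts <- 0L
  raw <- NULL
  last_err <- NULL
  while (attempts <= config$retries && is.null(raw)) {
    attempts <- attempts + 1L
    raw <- tryCatch(
      backend_complete(prompt, config),
      error = function(e) {
        last_err <<- e
        NULL
      }
    )
  }
  if (is.null(raw)) {
    pkb_stop("pkb_backend_unavailable",
             paste0("completion backend '", config$backend, "' unavailable after ",
                    attempts, " attempt(s): ", conditionMessage(last_err)))
  }
  structure(
    list(
      prompt = prompt, raw = raw, backend = config$backend, model = config$model,
      elapsed = proc.time()[["elapsed"]] - t0, attempts = attempts
    ),
    class = "pkb_completion"
  )
}

backend_complete <- function(prompt, config) {
  switch(config$backend,
    mock = {
      hit <- config$completions[[prompt]]
      if (is.null(hit)) config$fallback else hit
    },
    echo = prompt,
    `function` = config$fn(prompt),
    http = http_complete(prompt, config)
  )
}

# Minimal chat-completion POST via the curl binary; isolated here so that no
# other code path touches the network.
http_complete <- function(prompt, config) {
  if (is.null(config$url)) {
    pkb_stop("pkb_invalid_configuration", "http backend requires url")
  }
  body <- jsonlite::toJSON(list(
    model = config$model,
    temperature = config$temperature,
    max_tokens = config$max_tokens,
    messages = list(list(role = "user", content = prompt))
  ), auto_unbox = TRUE)
  key <- Sys.getenv(config$api_key_env, "")
  args <- c(
    "-sS", "--fail", "-X", "POST", config$url,
    "-H", "Content-Type: application/json",
    if (nzchar(key)) c("-H", paste0("Authorization: Bearer ", key)),
    "--max-time", as.character(config$timeout),
    "-d", body
  )
  out <- system2("curl", args, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stop("http request failed: ", paste(out, collapse = " "))
  parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
  parsed$choices[[1L]]$message$content %||% ""
}

#' Read / write mock-completion fixture files
#'
#' The fixture format is a YAML list of `{prompt, completion}` entries;
#' prompts are matched exactly (byte-for-byte) at completion time.
#'
#' @param path File path.
#' @return `read_completions()` returns a named list mapping prompt text to
#'   completion text, suitable for the `completions` argument of
#'   [completion_config()].
#' @export
read_completions <- function(path) {
  entries <- yaml::read_yaml(path)
  out <- lapply(entries, function(e) e$completion %||% "")
  names(out) <- vapply(entries, function(e) e$prompt, character(1L))
  out
}

#' @rdname read_completions
#' @param completions Named list of prompt -> completion.
#' @export
write_completions <- function(completions, path) {
  entries <- lapply(names(completions), function(p) {
    list(prompt = p, completion = completions[[p]])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Split a document into overlapping chunks
#'
#' Sliding-window chunking for long documents: chunk `k` starts at character
#' offset `k * (window - overlap)` and spans up to `window` characters. A
#' chunk start (other than the first) is snapped backward to just after the
#' nearest sentence or whitespace break when one exists within `overlap`
#' characters, so entities straddling a raw boundary stay intact in the next
#' chunk; snapping only ever increases the overlap, so every character of the
#' document remains covered by at least one chunk.
#'
#' @param text Document text.
#' @param window Chunk size in characters (default 2500).
#' @param overlap Overlap between consecutive chunks in characters (default
#'   250); must be smaller than `window`.
#' @return A data frame with columns `start`, `end` (1-based, inclusive) and
#'   `text`, one row per chunk in document order.
#' @export
chunk_text <- function(text, window = 2500L, overlap = 250L) {
  if (!is_string(text)) {
    pkb_stop("pkb_invalid_input", "text must be a single string")
  }
  window <- as.integer(window)
  overlap <- as.integer(overlap)
  if (is.na(window) || is.na(overlap) || overlap < 0L || window <= overlap) {
    pkb_stop("pkb_invalid_configuration",
             "chunking requires window > overlap >= 0")
  }
  n <- nchar(text)
  if (n <= window) {
    return(data.frame(start = 1L, end = n, text = text, stringsAsFactors = FALSE))
  }
  step <- window - overlap
  starts <- seq.int(0L, n - 1L, by = step)
  starts <- starts[starts < n]
  starts <- vapply(seq_along(starts), function(k) {
    s <- starts[[k]]
    if (k == 1L) return(s)
    snap_chunk_start(text, s, overlap)
  }, integer(1L))
  out <- lapply(starts, function(s) {
    e <- min(s + window, n)
    data.frame(start = s + 1L, end = e,
               text = substr(text, s + 1L, e), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Move a raw chunk start backward (at most `overlap` characters) to just
# after the last sentence end or, failing that, the last whitespace run in
# the look-back region.
snap_chunk_start <- function(text, s, overlap) {
  lo <- max(0L, s - overlap)
  region <- substr(text, lo + 1L, s + 1L)
  for (pat in c("[.!?][[:space:]]+", "[[:space:]]+")) {
    m <- gregexpr(pat, region)[[1L]]
    if (m[1L] != -1L) {
      ends <- m + attr(m, "match.length") - 1L
      cand <- lo + ends[length(ends)]  # 0-based offset just after the break
      if (cand <= s) return(as.integer(cand))
    }
  }
  as.integer(s)
}
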