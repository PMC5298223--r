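## Shared fixtures, built once per test run and cached (the FEM context
## dominates the cost of the forward-model and calibration tests).

.fixtureEnv <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- builder()
  .fixtureEnv[[name]]
}

defaultSpecFixture <- function() cachedFixture("spec", phantomSpec)

contextFixture <- function() cachedFixture("ctx", function()
  femContext(defaultSpecFixture()))

electrodesFixture <- function() contextFixture()$electrodes

unitForwardFixture <- function(name = "SM1") {
  cachedFixture(paste0("unit", name), function()
    unitForward(contextFixture(), makeSourceModel(name, defaultSpecFixture())))
}

recordingFixture <- function() cachedFixture("recording", function() {
  generateRecording(electrodesFixture(),
                    params = list(duration = 60, repRate = 1.0,
                                  scalpAmplitude = 30, background = 0.5),
                    seed = 11)
})

## A tiny single-channel sine recording for amplitude-statistic tests.
sineRecording <- function(freq = 200, amp = 10, rate = 1024, duration = 4,
                          offset = 0, nChannels = 1) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  x <- matrix(rep(amp * sin(2 * pi * freq * t) + offset, nChannels),
              ncol = nChannels)
  new("Recording", samples = x, rate = rate,
      channels = sprintf("C%02d", seq_len(nChannels)), band = c(1, 344))
}

centeredTrialSet <- function(centers, halfDur = 0.15, baselineOffset = -0.45) {
  new("TrialSet",
      events = data.frame(onset = centers - halfDur, end = centers + halfDur,
                          center = centers,
                          baseline_start = centers + baselineOffset - 0.1),
      baselineDur = 0.2)
}
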