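# Sudden-darkness startle protocol: 30-min habituation under white light,
# then six 1-s lights-off pulses at a 30-min inter-trial interval.
type: darkness
iti_s: 1800
n_trials: 6
habituation_s: 1800
pulse_ms: 1000
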