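# One monitor of red-eyed wild-type flies with the standard responder mixture.
n_flies: 16
preset: csorc
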