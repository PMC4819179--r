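0.732940492 -0.6754012288 -0.0814335022
0.6378508853 0.7238916047 -0.2629205065
0.2365258617 0.1407626539 0.9613747407
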