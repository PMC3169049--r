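((((((host06:0.06879646779,host08:0.06879646779):0.3097903964,host04:0.3785868642):0.2986397363,(host05:0.2322564771,host07:0.2322564771):0.4449701234):0.1326710726,host02:0.8098976731):0.001408482945,host03:0.811306156):0.143006135,host01:0.954312291);
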