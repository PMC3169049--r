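(((virus03:0.148327626,virus05:0.148327626):0.1182461166,virus06:0.09255462473):0.05735829121,(((virus04:0.003154765113,virus07:0.2092154514):0.003154765113,virus08:0.006309530226):0.1788089977,(virus02:0.09255926395,virus01:0.07752397729):0.09255926395):0.1388135059);
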