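> three hand-made structures in bar-bracket notation
(|||)
||((((|||(|||)||(||||)|))))||
(((((||||)))))|||
> dot dialect is auto-detected per file; this file uses bars only
|((|(|||)((||||))|))
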