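year,stage,survival
1,all,0.36
2,all,0.2735408468345733
3,all,0.20784609690826525
4,all,0.15792888155429907
5,all,0.12
1,early,0.6
2,early,0.5230113257230414
3,early,0.4559014113909555
4,early,0.39740266928431556
5,early,0.34641016151377546
1,advanced,0.3
2,advanced,0.21117322711245626
3,advanced,0.14583226828759266
4,advanced,0.09806043462179494
5,advanced,0.06339745962155613
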